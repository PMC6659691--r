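marker,trend
CCL3,up
CCL4,up
CCL5,down
CSF2,up
IL12B,down
IL1A,up
IL6,up
IL8,up
TNF,up
VEGFA,down
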