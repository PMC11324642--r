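LOC101212625
LOC101213580
LOC101213801
LOC101222503
LOC101205805
LOC101205000
LOC101203084
LOC101214385
LOC101210491
LOC101206239
LOC101210665
LOC101205431
LOC101206142
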