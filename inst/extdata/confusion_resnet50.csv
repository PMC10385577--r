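"",abnormal,normal,other
abnormal,473,6,4
normal,15,463,4
other,7,2,254
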