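"",abnormal,normal,other
abnormal,462,13,8
normal,8,473,1
other,9,2,252
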