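"",abnormal,normal,other
abnormal,476,5,2
normal,23,458,1
other,10,1,252
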