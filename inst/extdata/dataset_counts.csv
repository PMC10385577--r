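class,total,training,validation,testing
abnormal,3220,2254,483,483
normal,2813,1881,449,483
other,1749,1223,263,263
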