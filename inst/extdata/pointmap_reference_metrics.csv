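class,precision,recall,f1,iou,ap
abnormal,0.717,0.737,0.727,0.695,0.842
normal,0.650,0.641,0.645,0.590,0.706
other,0.851,0.975,0.909,0.831,1.000
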