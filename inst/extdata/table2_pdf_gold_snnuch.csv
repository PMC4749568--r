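neuron,layer_703,layer_723,layer_787,ambiguous,note
r1,0,2,0,FALSE,
l1,0,0,0,FALSE,
r2,0,0,0,FALSE,
l2,1,0,4,FALSE,
r3,0,0,0,FALSE,
l3,0,0,0,FALSE,
r4,0,0,7,FALSE,
l4,0,0,0,FALSE,
r5,0,0,0,FALSE,
l5,0,0,0,FALSE,
r6,2,0,0,FALSE,
l6,0,3,10,FALSE,
r7,0,0,0,FALSE,
l7,0,0,2,FALSE,
r8,0,1,2,FALSE,
l8,1,0,3,FALSE,
r9,0,0,0,FALSE,
l9,0,0,0,FALSE,
r10,0,0,0,FALSE,
l10,0,0,0,FALSE,
r11,0,0,0,FALSE,
l11,0,0,0,FALSE,
r12,0,3,0,FALSE,
l12,6,1,0,FALSE,
r13,1,3,2,FALSE,
l13,9,9,6,FALSE,
r14,0,0,0,FALSE,
l14,18,0,0,TRUE,printed as a run-on digit string; split 18/0/0 adopted but 1/8/0 cannot be excluded
r15,0,0,0,FALSE,
r16,0,0,0,FALSE,
r17,0,0,0,FALSE,
r18,0,0,0,FALSE,
r19,0,0,0,FALSE,
r20,0,0,0,FALSE,
l15,0,0,0,FALSE,
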