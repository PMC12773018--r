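id,input,modality,hemolysis
ex1,GLFDIVKKVVGALGSL,AA,1
ex2,ACDEFGHIKLMNPQRS,AA,0
ex3,KKKKRRRRKKKK,AA,1
ex4,SSTTGGNNQQ,AA,0
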