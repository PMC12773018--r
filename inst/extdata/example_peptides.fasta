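>amp1 synthetic amphipathic example
GLFDIVKKVVGALGSL
>cat1 synthetic polycationic example
KKKKRRRRKKKK
>neu1 synthetic neutral example
ACDEFGHIKLMNPQRS
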