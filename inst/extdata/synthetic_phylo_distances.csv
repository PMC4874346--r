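species,cheetah,leopard,lion,caracal,black_backed_jackal,brown_hyena
cheetah,0,21.6,21.6,18.8,110,60
leopard,21.6,0,8,21.6,110,60
lion,21.6,8,0,21.6,110,60
caracal,18.8,21.6,21.6,0,110,60
black_backed_jackal,110,110,110,110,0,110
brown_hyena,60,60,60,60,110,0
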