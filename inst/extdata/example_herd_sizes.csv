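herd_size,n_herds,n_animals
1,839,839
2,297,594
3,79,237
4,21,84
5,15,75
6,5,30
7 and above,4,37
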