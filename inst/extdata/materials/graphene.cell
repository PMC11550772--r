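name graphene
a1 2.4600000000 0.0000000000 0.0000000000
a2 -1.2300000000 2.1304224933 0.0000000000
atom C 0.0000000000 0.0000000000 0.0000000000
atom C 0.0000000000 1.4202816622 0.0000000000
source planar honeycomb, a = 2.46 A, C-C 1.420 A (standard graphene geometry)
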