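name MoS2
a1 3.1600000000 0.0000000000 0.0000000000
a2 -1.5800000000 2.7366402760 0.0000000000
atom Mo 0.0000000000 0.0000000000 0.0000000000
atom S -0.0000000000 1.8244268506 1.5860000000
atom S -0.0000000000 1.8244268506 -1.5860000000
source 1H-MoS2 monolayer, a = 3.160 A, Mo-S 2.417 A, S-S 3.172 A (trigonal prismatic)
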