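name WS2
a1 3.1550000000 0.0000000000 0.0000000000
a2 -1.5775000000 2.7323101489 0.0000000000
atom W 0.0000000000 0.0000000000 0.0000000000
atom S -0.0000000000 1.8215400993 1.5730000000
atom S -0.0000000000 1.8215400993 -1.5730000000
source 1H-WS2 monolayer, a = 3.155 A, W-S 2.405 A, S-S 3.146 A (trigonal prismatic)
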