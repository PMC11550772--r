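name germanene
a1 4.0600000000 0.0000000000 0.0000000000
a2 -2.0300000000 3.5160631394 0.0000000000
atom Ge 0.0000000000 0.0000000000 -0.3200000000
atom Ge -0.0000000000 2.3440420929 0.3200000000
source low-buckled germanene, a = 4.06 A, buckling 0.64 A (DFT literature values)
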