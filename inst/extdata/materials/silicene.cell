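name silicene
a1 3.8700000000 0.0000000000 0.0000000000
a2 -1.9350000000 3.3515183126 0.0000000000
atom Si 0.0000000000 0.0000000000 -0.2300000000
atom Si 0.0000000000 2.2343455418 0.2300000000
source low-buckled silicene, a = 3.87 A, buckling 0.46 A (DFT literature values)
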