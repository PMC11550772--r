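name graphane
a1 2.5400000000 0.0000000000 0.0000000000
a2 -1.2700000000 2.1997045256 0.0000000000
atom C 0.0000000000 0.0000000000 0.2301280441
atom C 0.0000000000 1.4664696837 -0.2301280441
atom H 0.0000000000 0.0000000000 1.3401280441
atom H 0.0000000000 1.4664696837 -1.3401280441
source chair graphane, a = 2.54 A, C-C 1.537 A, C-H 1.110 A (DFT literature values)
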