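name boron-nitride
a1 2.5040000000 0.0000000000 0.0000000000
a2 -1.2520000000 2.1685276111 0.0000000000
atom B 0.0000000000 0.0000000000 0.0000000000
atom N 0.0000000000 1.4456850741 0.0000000000
source planar h-BN monolayer, a = 2.504 A, B-N 1.446 A
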