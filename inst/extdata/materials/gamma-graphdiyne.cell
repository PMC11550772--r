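name gamma-graphdiyne
a1 9.4400000000 0.0000000000 0.0000000000
a2 -4.7200000000 8.1752798117 0.0000000000
atom C 1.4300000000 0.0000000000 0.0000000000
atom C 0.7150000000 1.2384163274 0.0000000000
atom C -0.7150000000 1.2384163274 0.0000000000
atom C 8.0100000000 0.0000000000 0.0000000000
atom C 4.0050000000 6.9368634843 0.0000000000
atom C -4.0050000000 6.9368634843 0.0000000000
atom C 2.8300000000 0.0000000000 0.0000000000
atom C 4.0500000000 0.0000000000 0.0000000000
atom C 5.3900000000 0.0000000000 0.0000000000
atom C 6.6100000000 0.0000000000 0.0000000000
atom C 1.4150000000 2.4508518927 0.0000000000
atom C 2.0250000000 3.5074028853 0.0000000000
atom C 2.6950000000 4.6678769264 0.0000000000
atom C 3.3050000000 5.7244279190 0.0000000000
atom C -1.4150000000 2.4508518927 0.0000000000
atom C -2.0250000000 3.5074028853 0.0000000000
atom C -2.6950000000 4.6678769264 0.0000000000
atom C -3.3050000000 5.7244279190 0.0000000000
source acetylenic carbon framework, bond lengths: aromatic 1.43, sp2-sp2 1.46, sp2-sp 1.40, triple 1.22, diyne single 1.34 A
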