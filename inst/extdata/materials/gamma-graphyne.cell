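name gamma-graphyne
a1 6.8800000000 0.0000000000 0.0000000000
a2 -3.4400000000 5.9582547780 0.0000000000
atom C 1.4300000000 0.0000000000 0.0000000000
atom C 0.7150000000 1.2384163274 0.0000000000
atom C -0.7150000000 1.2384163274 0.0000000000
atom C 5.4500000000 0.0000000000 0.0000000000
atom C 2.7250000000 4.7198384506 0.0000000000
atom C -2.7250000000 4.7198384506 0.0000000000
atom C 2.8300000000 0.0000000000 0.0000000000
atom C 4.0500000000 0.0000000000 0.0000000000
atom C 1.4150000000 2.4508518927 0.0000000000
atom C 2.0250000000 3.5074028853 0.0000000000
atom C -1.4150000000 2.4508518927 0.0000000000
atom C -2.0250000000 3.5074028853 0.0000000000
source acetylenic carbon framework, bond lengths: aromatic 1.43, sp2-sp2 1.46, sp2-sp 1.40, triple 1.22, diyne single 1.34 A
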