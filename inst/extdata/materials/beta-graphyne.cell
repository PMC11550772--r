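name beta-graphyne
a1 9.5000000000 0.0000000000 0.0000000000
a2 -4.7500000000 8.2272413360 0.0000000000
atom C 4.0200000000 0.0000000000 0.0000000000
atom C 5.4800000000 0.0000000000 0.0000000000
atom C 2.0100000000 3.4814221232 0.0000000000
atom C 2.7400000000 4.7458192127 0.0000000000
atom C -2.0100000000 3.4814221232 0.0000000000
atom C -2.7400000000 4.7458192127 0.0000000000
atom C 3.3200000000 1.2124355653 0.0000000000
atom C 2.7100000000 2.2689865579 0.0000000000
atom C 0.6100000000 3.4814221232 0.0000000000
atom C -0.6100000000 3.4814221232 0.0000000000
atom C 6.7900000000 2.2689865579 0.0000000000
atom C 6.1800000000 1.2124355653 0.0000000000
atom C 1.4300000000 7.0148057707 0.0000000000
atom C 2.0400000000 5.9582547780 0.0000000000
atom C 4.1400000000 4.7458192127 0.0000000000
atom C 5.3600000000 4.7458192127 0.0000000000
atom C -2.0400000000 5.9582547780 0.0000000000
atom C -1.4300000000 7.0148057707 0.0000000000
source acetylenic carbon framework, bond lengths: aromatic 1.43, sp2-sp2 1.46, sp2-sp 1.40, triple 1.22, diyne single 1.34 A
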