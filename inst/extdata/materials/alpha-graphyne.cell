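name alpha-graphyne
a1 6.9628442464 0.0000000000 0.0000000000
a2 -3.4814221232 6.0300000000 0.0000000000
atom C 0.0000000000 4.0200000000 0.0000000000
atom C 3.4814221232 2.0100000000 0.0000000000
atom C 0.0000000000 5.4200000000 0.0000000000
atom C 3.4814221232 0.6100000000 0.0000000000
atom C 1.2124355653 3.3200000000 0.0000000000
atom C 2.2689865579 2.7100000000 0.0000000000
atom C -1.2124355653 3.3200000000 0.0000000000
atom C 4.6938576885 2.7100000000 0.0000000000
source acetylenic carbon framework, bond lengths: aromatic 1.43, sp2-sp2 1.46, sp2-sp 1.40, triple 1.22, diyne single 1.34 A
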