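name hexagonal-bilayer-silica
a1 5.3268236940 0.0000000000 0.0000000000
a2 -2.6634118470 4.6131646405 0.0000000000
atom Si 0.0000000000 0.0000000000 1.6310000000
atom Si -0.0000000000 3.0754430936 1.6310000000
atom O -0.0000000000 1.5377215468 2.1746666667
atom O -1.3317059235 3.8443038671 2.1746666667
atom O 1.3317059235 3.8443038671 2.1746666667
atom Si 0.0000000000 0.0000000000 -1.6310000000
atom Si -0.0000000000 3.0754430936 -1.6310000000
atom O -0.0000000000 1.5377215468 -2.1746666667
atom O -1.3317059235 3.8443038671 -2.1746666667
atom O 1.3317059235 3.8443038671 -2.1746666667
atom O 0.0000000000 0.0000000000 0.0000000000
atom O -0.0000000000 3.0754430936 0.0000000000
source free-standing hexagonal silica bilayer, Si-O 1.631 A, ideal tetrahedra
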