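name haeckelite-silica
a1 10.6536473879 0.0000000000 0.0000000000
a2 -5.3268236940 9.2263292809 0.0000000000
atom Si 1.5722265367 1.5377215448 1.6310000000
atom Si 1.5722265367 1.5377215448 -1.6310000000
atom O 1.5722265367 1.5377215448 0.0000000000
atom Si 9.0814208513 1.5377215485 1.6310000000
atom Si 9.0814208513 1.5377215485 -1.6310000000
atom O 9.0814208513 1.5377215485 0.0000000000
atom Si -2.5857637886 4.5559229763 1.6310000000
atom Si -2.5857637886 4.5559229763 -1.6310000000
atom O -2.5857637886 4.5559229763 0.0000000000
atom Si -2.7410599054 7.7458493985 1.6310000000
atom Si -2.7410599054 7.7458493985 -1.6310000000
atom O -2.7410599054 7.7458493985 0.0000000000
atom Si -0.0000000008 9.2109598417 1.6310000000
atom Si -0.0000000008 9.2109598417 -1.6310000000
atom O -0.0000000008 9.2109598417 0.0000000000
atom Si 5.3268236948 3.0908125328 1.6310000000
atom Si 5.3268236948 3.0908125328 -1.6310000000
atom O 5.3268236948 3.0908125328 0.0000000000
atom Si 2.5857637885 4.5559229808 1.6310000000
atom Si 2.5857637885 4.5559229808 -1.6310000000
atom O 2.5857637885 4.5559229808 0.0000000000
atom Si 2.7410599055 7.7458493940 1.6310000000
atom Si 2.7410599055 7.7458493940 -1.6310000000
atom O 2.7410599055 7.7458493940 0.0000000000
atom O 0.0000000000 1.5377215466 2.1746666667
atom O 0.0000000000 1.5377215466 -2.1746666667
atom O 2.0789951626 0.0286208312 2.1746666667
atom O 2.0789951626 0.0286208312 -2.1746666667
atom O 2.0789951626 3.0468222628 2.1746666667
atom O 2.0789951626 3.0468222628 -2.1746666667
atom O 8.5746522253 3.0468222624 2.1746666667
atom O 8.5746522253 3.0468222624 -2.1746666667
atom O 8.5746522254 0.0286208308 2.1746666667
atom O 8.5746522254 0.0286208308 -2.1746666667
atom O 6.6973536471 3.8233677546 2.1746666667
atom O 6.6973536471 3.8233677546 -2.1746666667
atom O -2.6634118470 6.1508861874 2.1746666667
atom O -2.6634118470 6.1508861874 -2.1746666667
atom O -1.3705299531 8.4784046201 2.1746666667
atom O -1.3705299531 8.4784046201 -2.1746666667
atom O 5.3268236940 1.5377215468 2.1746666667
atom O 5.3268236940 1.5377215468 -2.1746666667
atom O 1.3705299524 8.4784046179 2.1746666667
atom O 1.3705299524 8.4784046179 -2.1746666667
atom O 3.9562937416 3.8233677568 2.1746666667
atom O 3.9562937416 3.8233677568 -2.1746666667
atom O 2.6634118470 6.1508861874 2.1746666667
atom O 2.6634118470 6.1508861874 -2.1746666667
source synthetic model geometry: Stone-Wales rearranged (5-7) silica bilayer, harmonically relaxed Si net, Si-O 1.631 A
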