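26
alpha-terpinene open-chain triene product tZc (synthetic builder geometry, Angstrom)
C 0.00000000 0.00000000 0.00000000
C 1.45000000 0.00000000 0.00000000
C 2.19931849 1.11091035 0.00000000
C -0.74931849 -0.55545517 0.96207658
C -0.20613893 -1.22766347 2.12637550
C 0.86360039 -0.79723420 2.80900896
C 2.15420734 -1.32442139 0.00000000
C -0.88302710 -2.48142598 2.59531256
C 3.67582584 -1.16449284 0.00000000
C 1.79701319 -2.16347525 -1.22853610
H -0.51172400 0.48120644 -0.83347400
H -1.83334736 -0.49848716 0.86340509
H 1.73866459 2.09878584 0.00000000
H 3.28782468 1.05386415 -0.00000000
H 1.39268883 0.10798526 2.51111110
H 1.23084413 -1.34179795 3.67888387
H 1.84364096 -1.85048573 0.90272079
H 4.00210040 -0.61690176 -0.88418828
H 4.16218146 -2.13997129 0.00000000
H 4.00210040 -0.61690176 0.88418828
H 0.72516480 -2.35927933 -1.25856591
H 2.32115835 -3.11886065 -1.20382591
H 2.07736286 -1.64030286 -2.14275419
H -1.92131337 -2.27920044 2.85830771
H -0.37714737 -2.88280488 3.47342455
H -0.86739225 -3.23946023 1.81221638
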