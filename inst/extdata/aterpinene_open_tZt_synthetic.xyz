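26
alpha-terpinene open-chain triene product tZt (synthetic builder geometry, Angstrom)
C 0.00000000 0.00000000 0.00000000
C 1.45000000 0.00000000 0.00000000
C 2.19931849 1.11091035 0.00000000
C -0.74931849 -0.55545517 0.96207658
C -0.20613893 -1.22766347 2.12637550
C -0.44044835 -2.51226282 2.42721368
C 2.15420734 -1.32442139 0.00000000
C 0.67165285 -0.43677802 3.05048686
C 3.67582584 -1.16449284 0.00000000
C 1.79701319 -2.16347525 -1.22853610
H -0.51172400 0.48120644 -0.83347400
H -1.83334736 -0.49848716 0.86340509
H 1.73866459 2.09878584 0.00000000
H 3.28782468 1.05386415 -0.00000000
H -1.07098344 -3.13213017 1.78980489
H -0.00624060 -2.96875839 3.31669410
H 1.84364096 -1.85048573 0.90272079
H 4.00210040 -0.61690176 -0.88418828
H 4.16218146 -2.13997129 0.00000000
H 4.00210040 -0.61690176 0.88418828
H 0.72516480 -2.35927933 -1.25856591
H 2.32115835 -3.11886065 -1.20382591
H 2.07736286 -1.64030286 -2.14275419
H 1.54726534 -0.06380680 2.51917223
H 1.01052392 -1.05779949 3.87970259
H 0.12732125 0.41507539 3.45810051
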