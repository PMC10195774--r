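26
alpha-terpinene closed-ring reactant, rotamer 1 (synthetic builder geometry, Angstrom)
C 0.00000000 0.00000000 0.00000000
C 1.33800000 0.00000000 0.00000000
C 2.08800000 1.29903811 0.00000000
C -0.73500000 1.20258101 -0.41770074
C -0.09273399 2.36976742 -0.54185496
C 1.23422236 2.57060910 0.12810731
C 2.13817809 -1.28055263 -0.00000000
C -0.75063412 3.43836554 -1.36360035
C 1.84038348 -2.14247920 -1.22853610
C 1.84038348 -2.14247920 1.22853610
H -0.52322119 -0.95084692 0.10114208
H -1.82500000 1.20258101 -0.41770074
H 2.64144018 1.39964645 -0.93363908
H 2.78439632 1.31711069 0.83833498
H 1.07888931 2.79210378 1.18400113
H 1.75793882 3.40196108 -0.34377716
H 3.19103724 -0.99843987 0.00000000
H 0.78480466 -2.41257467 -1.25856591
H 2.42989617 -3.05897480 -1.20382591
H 2.08355557 -1.60102503 -2.14275419
H 2.08355557 -1.60102503 2.14275419
H 2.42989617 -3.05897480 1.20382591
H 0.78480466 -2.41257467 1.25856591
H -0.90039337 3.09487911 -2.38716727
H -0.13243500 4.33575992 -1.38836276
H -1.72134922 3.70028105 -0.94263424
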