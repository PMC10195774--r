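26
alpha-terpinene open-chain triene product cZc (synthetic builder geometry, Angstrom)
C 0.00000000 0.00000000 0.00000000
C 1.45000000 0.00000000 0.00000000
C 2.19931849 1.11091035 0.00000000
C -0.74931849 0.85100670 0.71407941
C -0.20613893 1.88088956 1.57825373
C 0.66535485 1.64531194 2.56850712
C 2.15420734 -1.32442139 0.00000000
C -0.64667983 3.29641976 1.34978498
C 1.79701319 -2.16347525 -1.22853610
C 1.79701319 -2.16347525 1.22853610
H -0.51172400 -0.73725104 -0.61862707
H -1.83334736 0.76372664 0.64084274
H 1.73866459 2.09878584 0.00000000
H 3.28782468 1.05386415 -0.00000000
H 1.01815372 0.63536842 2.77742587
H 1.04277866 2.45786549 3.18931948
H 3.22418097 -1.11643958 0.00000000
H 0.72516480 -2.35927933 -1.25856591
H 2.32115835 -3.11886065 -1.20382591
H 2.07736286 -1.64030286 -2.14275419
H 2.07736286 -1.64030286 2.14275419
H 2.32115835 -3.11886065 1.20382591
H 0.72516480 -2.35927933 1.25856591
H -0.38354602 3.62029242 0.34282565
H -0.16618928 3.96565372 2.06347591
H -1.72663607 3.38400262 1.46862845
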