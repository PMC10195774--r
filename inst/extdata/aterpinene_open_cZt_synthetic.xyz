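26
alpha-terpinene open-chain triene product cZt (synthetic builder geometry, Angstrom)
C 0.00000000 0.00000000 0.00000000
C 1.45000000 0.00000000 0.00000000
C 2.19931849 1.11091035 0.00000000
C -0.74931849 0.85100670 0.71407941
C -0.20613893 1.88088956 1.57825373
C -0.44044835 3.19091080 1.42159029
C 2.15420734 -1.32442139 0.00000000
C 0.67165285 1.45376503 2.71713311
C 1.79701319 -2.16347525 -1.22853610
C 1.79701319 -2.16347525 1.22853610
H -0.51172400 -0.73725104 -0.61862707
H -1.83334736 0.76372664 0.64084274
H 1.73866459 2.09878584 0.00000000
H 3.28782468 1.05386415 -0.00000000
H -1.07098344 3.55538893 0.61061484
H -0.00624060 3.92409654 2.10129780
H 3.22418097 -1.11643958 0.00000000
H 0.72516480 -2.35927933 -1.25856591
H 2.32115835 -3.11886065 -1.20382591
H 2.07736286 -1.64030286 -2.14275419
H 2.07736286 -1.64030286 2.14275419
H 2.32115835 -3.11886065 1.20382591
H 0.72516480 -2.35927933 1.25856591
H 0.12732125 0.79269675 3.39151567
H 1.01052392 2.32094281 3.28393916
H 1.54726534 0.92156643 2.34542434
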