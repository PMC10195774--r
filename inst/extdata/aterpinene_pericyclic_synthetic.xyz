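26
alpha-terpinene S1 pericyclic minimum anchor (synthetic builder geometry, Angstrom)
C 0.00000000 0.00000000 0.00000000
C 1.34500000 0.00000000 0.00000000
C 2.09250000 1.29470798 0.00000000
C -0.73100000 1.16942072 -0.48532276
C -0.08846845 2.33729680 -0.66488796
C 1.18484454 2.61051147 0.06931417
C 2.14517809 -1.25812110 0.23863426
C -0.28480938 3.04161053 -1.97461786
C 1.84738348 -2.33389011 -0.80775927
C 1.84738348 -1.87600840 1.60627225
H -0.52071330 -0.94645720 0.14552124
H -1.82100000 1.16942072 -0.48532276
H 2.68187554 1.37456904 -0.91343236
H 2.75577361 1.33190397 0.86416698
H 0.96072667 2.85697549 1.10716131
H 1.70231259 3.44786297 -0.39884101
H 3.19803724 -0.98095013 0.18606183
H 0.79180466 -2.60485043 -0.78693006
H 2.43689617 -3.22972659 -0.61269062
H 2.09055557 -1.97228751 -1.80686431
H 2.09055557 -1.17367204 2.40357455
H 2.43689617 -2.78105451 1.75278621
H 0.79180466 -2.13577647 1.68610900
H 0.04877506 2.41268732 -2.80001293
H 0.28465978 3.97073925 -1.99752415
H -1.33775985 3.27911481 -2.12623253
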