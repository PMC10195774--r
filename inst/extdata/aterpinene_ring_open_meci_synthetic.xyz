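26
alpha-terpinene ring-open S0/S1 MECI anchor (synthetic builder geometry, Angstrom)
C 0.00000000 0.00000000 0.00000000
C 1.40000000 0.00000000 0.00000000
C 2.15248536 1.20422830 0.00000000
C -0.70500000 0.98623109 -0.72001614
C -0.11944315 2.23666462 -0.95140144
C 0.71249464 2.86765238 0.01095709
C 2.20017809 -1.25812110 0.23863426
C 0.14138321 2.62633746 -2.37622589
C 1.90238348 -2.33389011 -0.80775927
C 1.90238348 -1.87600840 1.60627225
H -0.45589783 -0.97355182 0.18014999
H -1.79500000 0.98623109 -0.72001614
H 2.77703391 1.24301049 -0.89248812
H 2.78489847 1.23809617 0.88713394
H 0.14798010 3.03052806 0.92905014
H 1.05679552 3.82588037 -0.37808792
H 3.25303724 -0.98095013 0.18606183
H 0.84680466 -2.60485043 -0.78693006
H 2.49189617 -3.22972659 -0.61269062
H 2.14555557 -1.97228751 -1.80686431
H 2.14555557 -1.17367204 2.40357455
H 2.49189617 -2.78105451 1.75278621
H 0.84680466 -2.13577647 1.68610900
H 0.81616194 1.91312718 -2.84962292
H 0.59676486 3.61549124 -2.42420876
H -0.78964875 2.64789051 -2.94263118
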