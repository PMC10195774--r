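C1 1
C2 6
C3 2
C4 5
C5 4
C6 0
C7 8
C8 9
C9 3
C10 7
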