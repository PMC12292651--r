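>SYN_ZIC synthetic Zic-like test matrix (not a curated JASPAR entry)
A  [ 10 10 40 10 10 10 10 10 10 ]
C  [ 70 70 10 10 70 10 10 10 10 ]
G  [ 10 10 10 70 10 10 70 10 70 ]
T  [ 10 10 40 10 10 70 10 70 10 ]
>SYN_FOXH1 synthetic Foxh1-like test matrix (not a curated JASPAR entry)
A  [ 10 10 10 10 10 70 10 10 ]
C  [ 10 10 10 10 10 10 10 10 ]
G  [ 10 70 10 40 70 10 10 10 ]
T  [ 70 10 70 40 10 10 70 70 ]
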