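MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF PLANT1 synthetic_AP1_like
letter-probability matrix: alength= 4 w= 8 nsites= 100
0.04000000  0.04000000  0.04000000  0.88000000
0.04000000  0.04000000  0.88000000  0.04000000
0.88000000  0.04000000  0.04000000  0.04000000
0.04000000  0.88000000  0.04000000  0.04000000
0.04000000  0.04000000  0.04000000  0.88000000
0.04000000  0.88000000  0.04000000  0.04000000
0.88000000  0.04000000  0.04000000  0.04000000
0.04000000  0.04000000  0.88000000  0.04000000

MOTIF DECOY01 decoy_AGAAGTCT
letter-probability matrix: alength= 4 w= 8 nsites= 100
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.80000000  0.06666667  0.06666667  0.06666667
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.80000000  0.06666667  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000

MOTIF DECOY02 decoy_TGGAGCGT
letter-probability matrix: alength= 4 w= 8 nsites= 100
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.80000000  0.06666667  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000

MOTIF DECOY03 decoy_CATGACTG
letter-probability matrix: alength= 4 w= 8 nsites= 100
0.06666667  0.80000000  0.06666667  0.06666667
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.06666667  0.80000000  0.06666667
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.80000000  0.06666667  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.06666667  0.80000000  0.06666667

MOTIF DECOY04 decoy_GCAAGGAT
letter-probability matrix: alength= 4 w= 8 nsites= 100
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.80000000  0.06666667  0.06666667
0.80000000  0.06666667  0.06666667  0.06666667
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000

MOTIF DECOY05 decoy_ATCAGTTC
letter-probability matrix: alength= 4 w= 8 nsites= 100
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.80000000  0.06666667  0.06666667
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.80000000  0.06666667  0.06666667

MOTIF DECOY06 decoy_GCTTTTTG
letter-probability matrix: alength= 4 w= 8 nsites= 100
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.80000000  0.06666667  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.06666667  0.80000000  0.06666667

MOTIF DECOY07 decoy_AGTGCTAA
letter-probability matrix: alength= 4 w= 8 nsites= 100
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.80000000  0.06666667  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000
0.80000000  0.06666667  0.06666667  0.06666667
0.80000000  0.06666667  0.06666667  0.06666667

MOTIF DECOY08 decoy_CTATCGGT
letter-probability matrix: alength= 4 w= 8 nsites= 100
0.06666667  0.80000000  0.06666667  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000
0.06666667  0.80000000  0.06666667  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000

MOTIF DECOY09 decoy_ATAGGGGC
letter-probability matrix: alength= 4 w= 8 nsites= 100
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.06666667  0.06666667  0.80000000
0.80000000  0.06666667  0.06666667  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.06666667  0.80000000  0.06666667
0.06666667  0.80000000  0.06666667  0.06666667

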