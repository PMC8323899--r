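ATOM      1  N   ALA A   1       4.800   0.350   0.397  1.00  0.00           N
ATOM      2  CA  ALA A   1       6.000  -0.350  -0.212  1.00  0.00           C
ATOM      3  C   ALA A   1       7.200   0.350  -0.220  1.00  0.00           C
ATOM      4  N   ALA A   2      10.800   0.350  -0.102  1.00  0.00           N
ATOM      5  CA  ALA A   2      12.000  -0.350  -0.309  1.00  0.00           C
ATOM      6  C   ALA A   2      13.200   0.350   0.359  1.00  0.00           C
ATOM      7  N   ALA A   3      16.800   0.350  -0.370  1.00  0.00           N
ATOM      8  CA  ALA A   3      18.000  -0.350   0.292  1.00  0.00           C
ATOM      9  C   ALA A   3      19.200   0.350   0.128  1.00  0.00           C
ATOM     10  N   ALA A   4      22.800   0.350   0.198  1.00  0.00           N
ATOM     11  CA  ALA A   4      24.000  -0.350   0.234  1.00  0.00           C
ATOM     12  C   ALA A   4      25.200   0.350  -0.392  1.00  0.00           C
ATOM     13  N   ALA A   5      28.800   0.350   0.319  1.00  0.00           N
ATOM     14  CA  ALA A   5      30.000  -0.350  -0.352  1.00  0.00           C
ATOM     15  C   ALA A   5      31.200   0.350  -0.027  1.00  0.00           C
ATOM     16  N   ALA A   6      34.800   0.350  -0.280  1.00  0.00           N
ATOM     17  CA  ALA A   6      36.000  -0.350  -0.143  1.00  0.00           C
ATOM     18  C   ALA A   6      37.200   0.350   0.399  1.00  0.00           C
TER
ATOM     19  N   ALA B   1       4.800   7.350  -0.247  1.00  0.00           N
ATOM     20  CA  ALA B   1       6.000   6.650   0.389  1.00  0.00           C
ATOM     21  C   ALA B   1       7.200   7.350  -0.076  1.00  0.00           C
ATOM     22  N   ALA B   2      10.800  18.350   0.344  1.00  0.00           N
ATOM     23  CA  ALA B   2      12.000  17.650   0.043  1.00  0.00           C
ATOM     24  C   ALA B   2      13.200  18.350  -0.380  1.00  0.00           C
ATOM     25  N   ALA B   4      16.800  18.350   0.159  1.00  0.00           N
ATOM     26  CA  ALA B   4      18.000  17.650  -0.400  1.00  0.00           C
ATOM     27  C   ALA B   4      19.200  18.350   0.174  1.00  0.00           C
ATOM     28  N   ALA B   5      22.800  18.350  -0.385  1.00  0.00           N
ATOM     29  CA  ALA B   5      24.000  17.650   0.060  1.00  0.00           C
ATOM     30  C   ALA B   5      25.200  18.350   0.335  1.00  0.00           C
ATOM     31  N   ALA B   6      28.800   7.350  -0.060  1.00  0.00           N
ATOM     32  CA  ALA B   6      30.000   6.650   0.384  1.00  0.00           C
ATOM     33  C   ALA B   6      31.200   7.350  -0.260  1.00  0.00           C
ATOM     34  N   ALA B   7      34.800   7.350   0.400  1.00  0.00           N
ATOM     35  CA  ALA B   7      36.000   6.650  -0.159  1.00  0.00           C
ATOM     36  C   ALA B   7      37.200   7.350  -0.268  1.00  0.00           C
ATOM     37  N   ALA B   8      40.800  18.350  -0.043  1.00  0.00           N
ATOM     38  CA  ALA B   8      42.000  17.650  -0.343  1.00  0.00           C
ATOM     39  C   ALA B   8      43.200  18.350   0.329  1.00  0.00           C
ATOM     40  N   ALA B   9      46.800  18.350  -0.389  1.00  0.00           N
ATOM     41  CA  ALA B   9      48.000  17.650   0.248  1.00  0.00           C
ATOM     42  C   ALA B   9      49.200  18.350   0.183  1.00  0.00           C
ATOM     43  N   ALA B  10      52.800  18.350   0.144  1.00  0.00           N
ATOM     44  CA  ALA B  10      54.000  17.650   0.280  1.00  0.00           C
ATOM     45  C   ALA B  10      55.200  18.350  -0.376  1.00  0.00           C
ATOM     46  N   ALA B  11      58.800  18.350   0.352  1.00  0.00           N
ATOM     47  CA  ALA B  11      60.000  17.650  -0.320  1.00  0.00           C
ATOM     48  C   ALA B  11      61.200  18.350  -0.086  1.00  0.00           C
ATOM     49  N   ALA B  12      64.800  18.350  -0.234  1.00  0.00           N
ATOM     50  CA  ALA B  12      66.000  17.650  -0.197  1.00  0.00           C
ATOM     51  C   ALA B  12      67.200  18.350   0.398  1.00  0.00           C
ATOM     52  N   ALA B  13      70.800  18.350  -0.291  1.00  0.00           N
ATOM     53  CA  ALA B  13      72.000  17.650   0.370  1.00  0.00           C
ATOM     54  C   ALA B  13      73.200  18.350  -0.017  1.00  0.00           C
END
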