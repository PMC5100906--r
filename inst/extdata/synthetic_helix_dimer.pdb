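ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N  
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C  
ATOM      3  C   ALA A   1       2.009   1.422   0.000  1.00  0.00           C  
ATOM      4  O   ALA A   1       2.910   1.749  -0.773  1.00  0.00           O  
ATOM      5  N   ALA A   2       1.463   2.263   0.872  1.00  0.00           N  
ATOM      6  CA  ALA A   2       1.899   3.650   0.974  1.00  0.00           C  
ATOM      7  C   ALA A   2       1.768   4.370  -0.364  1.00  0.00           C  
ATOM      8  O   ALA A   2       2.689   5.059  -0.802  1.00  0.00           O  
ATOM      9  N   ALA A   3       0.618   4.205  -1.008  1.00  0.00           N  
ATOM     10  CA  ALA A   3       0.364   4.838  -2.297  1.00  0.00           C  
ATOM     11  C   ALA A   3       1.421   4.443  -3.323  1.00  0.00           C  
ATOM     12  O   ALA A   3       1.961   5.294  -4.030  1.00  0.00           O  
ATOM     13  N   ALA A   4       1.711   3.149  -3.398  1.00  0.00           N  
ATOM     14  CA  ALA A   4       2.704   2.639  -4.337  1.00  0.00           C  
ATOM     15  C   ALA A   4       4.057   3.309  -4.126  1.00  0.00           C  
ATOM     16  O   ALA A   4       4.701   3.745  -5.081  1.00  0.00           O  
ATOM     17  N   ALA A   5       4.484   3.388  -2.870  1.00  0.00           N  
ATOM     18  CA  ALA A   5       5.761   4.005  -2.531  1.00  0.00           C  
ATOM     19  C   ALA A   5       5.830   5.442  -3.035  1.00  0.00           C  
ATOM     20  O   ALA A   5       6.820   5.851  -3.640  1.00  0.00           O  
ATOM     21  N   ALA A   6       4.771   6.204  -2.781  1.00  0.00           N  
ATOM     22  CA  ALA A   6       4.709   7.597  -3.208  1.00  0.00           C  
ATOM     23  C   ALA A   6       4.899   7.721  -4.716  1.00  0.00           C  
ATOM     24  O   ALA A   6       5.674   8.553  -5.187  1.00  0.00           O  
ATOM     25  N   ALA A   7       4.187   6.887  -5.467  1.00  0.00           N  
ATOM     26  CA  ALA A   7       4.276   6.902  -6.922  1.00  0.00           C  
ATOM     27  C   ALA A   7       5.712   6.685  -7.389  1.00  0.00           C  
ATOM     28  O   ALA A   7       6.209   7.406  -8.254  1.00  0.00           O  
ATOM     29  N   ALA A   8       6.372   5.687  -6.812  1.00  0.00           N  
ATOM     30  CA  ALA A   8       7.751   5.373  -7.167  1.00  0.00           C  
ATOM     31  C   ALA A   8       8.660   6.581  -6.968  1.00  0.00           C  
ATOM     32  O   ALA A   8       9.464   6.915  -7.839  1.00  0.00           O  
ATOM     33  N   ALA B 101      12.000   8.000   0.000  1.00  0.00           N  
ATOM     34  CA  ALA B 101      13.458   8.000   0.000  1.00  0.00           C  
ATOM     35  C   ALA B 101      14.009   9.422   0.000  1.00  0.00           C  
ATOM     36  O   ALA B 101      14.910   9.749  -0.773  1.00  0.00           O  
ATOM     37  N   ALA B 102      13.463  10.263   0.872  1.00  0.00           N  
ATOM     38  CA  ALA B 102      13.899  11.650   0.974  1.00  0.00           C  
ATOM     39  C   ALA B 102      13.768  12.370  -0.364  1.00  0.00           C  
ATOM     40  O   ALA B 102      14.689  13.059  -0.802  1.00  0.00           O  
ATOM     41  N   ALA B 103      12.618  12.205  -1.008  1.00  0.00           N  
ATOM     42  CA  ALA B 103      12.364  12.838  -2.297  1.00  0.00           C  
ATOM     43  C   ALA B 103      13.421  12.443  -3.323  1.00  0.00           C  
ATOM     44  O   ALA B 103      13.961  13.294  -4.030  1.00  0.00           O  
ATOM     45  N   ALA B 104      13.711  11.149  -3.398  1.00  0.00           N  
ATOM     46  CA  ALA B 104      14.704  10.639  -4.337  1.00  0.00           C  
ATOM     47  C   ALA B 104      16.057  11.309  -4.126  1.00  0.00           C  
ATOM     48  O   ALA B 104      16.701  11.745  -5.081  1.00  0.00           O  
ATOM     49  N   ALA B 105      16.484  11.388  -2.870  1.00  0.00           N  
ATOM     50  CA  ALA B 105      17.761  12.005  -2.531  1.00  0.00           C  
ATOM     51  C   ALA B 105      17.830  13.442  -3.035  1.00  0.00           C  
ATOM     52  O   ALA B 105      18.820  13.851  -3.640  1.00  0.00           O  
ATOM     53  N   ALA B 106      16.771  14.204  -2.781  1.00  0.00           N  
ATOM     54  CA  ALA B 106      16.709  15.597  -3.208  1.00  0.00           C  
ATOM     55  C   ALA B 106      16.899  15.721  -4.716  1.00  0.00           C  
ATOM     56  O   ALA B 106      17.674  16.553  -5.187  1.00  0.00           O  
END   
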