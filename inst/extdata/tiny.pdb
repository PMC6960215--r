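REMARK synthetic reader fixture: hydroxylated fragment + one water
CRYST1   30.000   30.000   30.000  90.00  90.00  90.00 P 1           1
ATOM      1  C   POL     1      10.000  10.000  10.000  1.00  0.00           C
ATOM      2  O   POL     1      11.400  10.000  10.000  1.00  0.00           O
ATOM      3  H   POL     1      12.200  10.600  10.000  1.00  0.00           H
ATOM      4  OW  SOL     2      20.000  20.000  20.000  1.00  0.00           O
ATOM      5  HW1 SOL     2      21.000  20.000  20.000  1.00  0.00           H
ATOM      6  HW2 SOL     2      19.750  20.970  20.000  1.00  0.00           H
END
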