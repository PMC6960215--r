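hydroxylated fragment + one water, synthetic reader fixture
    6
    1POL      C    1   1.000   1.000   1.000
    1POL      O    2   1.140   1.000   1.000
    1POL      H    3   1.220   1.060   1.000
    2SOL     OW    4   2.000   2.000   2.000
    2SOL    HW1    5   2.100   2.000   2.000
    2SOL    HW2    6   1.975   2.097   2.000
   3.00000   3.00000   3.00000
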