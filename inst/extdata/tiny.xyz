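6
Lattice="30.0 0 0 0 30.0 0 0 0 30.0" Properties=species:S:1:pos:R:3 synthetic reader fixture
C:POL 10.0 10.0 10.0 1
O:POL 11.4 10.0 10.0 1
H:POL 12.2 10.6 10.0 1
OW:SOL 20.0 20.0 20.0 2
HW1:SOL 21.0 20.0 20.0 2
HW2:SOL 19.75 20.97 20.0 2
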