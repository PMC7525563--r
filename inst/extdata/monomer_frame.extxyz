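3
Lattice="20 0 0 0 20 0 0 0 20" Properties=species:S:1:pos:R:3:role:S:1:charge:R:1:chain:I:1:monomer:I:1 step=0 eps_r=47
S 9.94045554 10.08883170 9.91957988 S+ 1.88269319 1 1
O 9.87172534 10.09458328 10.31076855 O- -0.94134660 1 1
O 10.18781912 9.81658502 9.76965157 O- -0.94134660 1 1
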