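code NH2
class cap
letter -
fullname amide_C-cap
formal_charge 0
chiral no
amide_h no
atom N    N   -0.4640  1.824  0.1700 sp2
atom HN1  H    0.2320  0.600  0.0157 sp3
atom HN2  H    0.2320  0.600  0.0157 sp3
zmat N    @C   @CA  @N    1.335  116.6 psi
zmat HN1  N    @C   @CA   1.010  119.0 0
zmat HN2  N    @C   @CA   1.010  119.0 180
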