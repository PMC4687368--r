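code NME
class cap
letter -
fullname N-methylamide_C-cap
formal_charge 0
chiral no
amide_h no
atom N    N   -0.4150  1.824  0.1700 sp2
atom H    H    0.2720  0.600  0.0157 sp3
atom CH3  C   -0.1510  1.908  0.0860 sp3
atom HH31 H    0.0980  1.387  0.0157 sp3
atom HH32 H    0.0980  1.387  0.0157 sp3
atom HH33 H    0.0980  1.387  0.0157 sp3
zmat N    @C   @CA  @N    1.335  116.6 psi
zmat H    N    @C   @CA   1.010  119.0 0
zmat CH3  N    @C   @CA   1.470  121.0 180
zmat HH31 CH3  N    @C    1.090  109.5 60
zmat HH32 CH3  N    @C    1.090  109.5 180
zmat HH33 CH3  N    @C    1.090  109.5 -60
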