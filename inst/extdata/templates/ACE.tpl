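code ACE
class cap
letter -
fullname acetyl_N-cap
formal_charge 0
chiral no
amide_h no
atom CH3  C   -0.3660  1.908  0.0860 sp3
atom HH31 H    0.1120  1.387  0.0157 sp3
atom HH32 H    0.1120  1.387  0.0157 sp3
atom HH33 H    0.1120  1.387  0.0157 sp3
atom C    C    0.5980  1.908  0.0860 sp2
atom O    O   -0.5680  1.661  0.2100 sp2
zmat C    @N   @CA  @C    1.335  121.0 180
zmat CH3  C    @N   @CA   1.510  116.6 180
zmat O    C    @N   @CA   1.230  123.0 0
zmat HH31 CH3  C    @N    1.090  109.5 60
zmat HH32 CH3  C    @N    1.090  109.5 180
zmat HH33 CH3  C    @N    1.090  109.5 -60
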