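code GLY
class natural
letter G
fullname glycine
formal_charge 0
chiral no
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C   -0.0056  1.908  0.0860 sp3
atom C    C    0.5973  1.908  0.0860 sp2
atom O    O   -0.5679  1.661  0.2100 sp2
atom HA2  H    0.0600  1.387  0.0157 sp3
atom HA3  H    0.0600  1.387  0.0157 sp3
zmat HA2  CA   N    C     1.090  109.5 119
zmat HA3  CA   N    C     1.090  109.5 -122.5
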