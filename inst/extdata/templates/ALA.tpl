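code ALA
class natural
letter A
fullname alanine
formal_charge 0
chiral yes
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C   -0.0256  1.908  0.0860 sp3
atom C    C    0.5973  1.908  0.0860 sp2
atom O    O   -0.5679  1.661  0.2100 sp2
atom HA   H    0.0600  1.387  0.0157 sp3
atom CB   C   -0.1000  1.908  0.0860 sp3
atom HB1  H    0.0600  1.387  0.0157 sp3
atom HB2  H    0.0600  1.387  0.0157 sp3
atom HB3  H    0.0600  1.387  0.0157 sp3
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  110.5 -122.5
zmat HB1  CB   CA   N     1.090  109.5 60
zmat HB2  CB   CA   N     1.090  109.5 180
zmat HB3  CB   CA   N     1.090  109.5 -60
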