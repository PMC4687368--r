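code SEP
class ptm
letter S
fullname phosphoserine_(synthetic_template)
formal_charge -2
chiral yes
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C   -0.9656  1.908  0.0860 sp3
atom C    C    0.5973  1.908  0.0860 sp2
atom O    O   -0.5679  1.661  0.2100 sp2
atom HA   H    0.0600  1.387  0.0157 sp3
atom CB   C   -0.1000  1.908  0.0860 sp3
atom OG   O   -0.5500  1.661  0.2100 sp3
atom HB2  H    0.0600  1.387  0.0157 sp3
atom HB3  H    0.0600  1.387  0.0157 sp3
atom P    P    1.2000  2.100  0.2000 sp3
atom O1P  O   -0.5500  1.661  0.2100 sp3
atom O2P  O   -0.5500  1.661  0.2100 sp3
atom O3P  O   -0.5500  1.661  0.2100 sp3
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  110.5 -122.5
zmat OG   CB   CA   N     1.417  110.5 chi1
zmat HB2  CB   CA   N     1.090  109.0 chi1+121
zmat HB3  CB   CA   N     1.090  109.0 chi1-121
zmat P    OG   CB   CA    1.610  119.0 chi2
zmat O1P  P    OG   CB    1.490  108.0 chi3
zmat O2P  P    OG   CB    1.490  108.0 chi3+120
zmat O3P  P    OG   CB    1.490  108.0 chi3-120
chi chi1 N CA CB OG
chi chi2 CA CB OG P
chi chi3 CB OG P O1P
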