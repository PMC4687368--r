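code GLN
class natural
letter Q
fullname glutamine
formal_charge 0
chiral yes
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C    0.4044  1.908  0.0860 sp3
atom C    C    0.5973  1.908  0.0860 sp2
atom O    O   -0.5679  1.661  0.2100 sp2
atom HA   H    0.0600  1.387  0.0157 sp3
atom CB   C   -0.1000  1.908  0.0860 sp3
atom CG   C   -0.1000  1.908  0.0860 sp2
atom HB2  H    0.0600  1.387  0.0157 sp3
atom HB3  H    0.0600  1.387  0.0157 sp3
atom CD   C   -0.1000  1.908  0.0860 sp2
atom HG2  H    0.0600  1.387  0.0157 sp3
atom HG3  H    0.0600  1.387  0.0157 sp3
atom OE1  O   -0.5500  1.661  0.2100 sp2
atom NE2  N   -0.5000  1.824  0.1700 sp2
atom HE21 H    0.3800  0.600  0.0157 sp3
atom HE22 H    0.3800  0.600  0.0157 sp3
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  110.5 -122.5
zmat CG   CB   CA   N     1.526  114.0 chi1
zmat HB2  CB   CA   N     1.090  109.0 chi1+121
zmat HB3  CB   CA   N     1.090  109.0 chi1-121
zmat CD   CG   CB   CA    1.522  112.6 chi2
zmat HG2  CG   CB   CA    1.090  109.0 chi2+121
zmat HG3  CG   CB   CA    1.090  109.0 chi2-121
zmat OE1  CD   CG   CB    1.230  120.5 chi3
zmat NE2  CD   CG   CB    1.335  116.5 chi3+180
zmat HE21 NE2  CD   CG    1.010  119.0 0
zmat HE22 NE2  CD   CG    1.010  119.0 180
chi chi1 N CA CB CG
chi chi2 CA CB CG CD
chi chi3 CB CG CD OE1
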