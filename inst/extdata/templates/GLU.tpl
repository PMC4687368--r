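code GLU
class natural
letter E
fullname glutamate
formal_charge -1
chiral yes
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C    0.2144  1.908  0.0860 sp3
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
atom OE2  O   -0.5500  1.661  0.2100 sp2
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  110.5 -122.5
zmat CG   CB   CA   N     1.526  114.0 chi1
zmat HB2  CB   CA   N     1.090  109.0 chi1+121
zmat HB3  CB   CA   N     1.090  109.0 chi1-121
zmat CD   CG   CB   CA    1.527  112.6 chi2
zmat HG2  CG   CB   CA    1.090  109.0 chi2+121
zmat HG3  CG   CB   CA    1.090  109.0 chi2-121
zmat OE1  CD   CG   CB    1.250  117.0 chi3
zmat OE2  CD   CG   CB    1.250  117.0 chi3+180
chi chi1 N CA CB CG
chi chi2 CA CB CG CD
chi chi3 CB CG CD OE1
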