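code TYR
class natural
letter Y
fullname tyrosine
formal_charge 0
chiral yes
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C    0.5644  1.908  0.0860 sp3
atom C    C    0.5973  1.908  0.0860 sp2
atom O    O   -0.5679  1.661  0.2100 sp2
atom HA   H    0.0600  1.387  0.0157 sp3
atom CB   C   -0.1000  1.908  0.0860 sp3
atom CG   C   -0.1000  1.908  0.0860 sp2
atom HB2  H    0.0600  1.387  0.0157 sp3
atom HB3  H    0.0600  1.387  0.0157 sp3
atom CD1  C   -0.1000  1.908  0.0860 sp2
atom CD2  C   -0.1000  1.908  0.0860 sp2
atom CE1  C   -0.1000  1.908  0.0860 sp2
atom CE2  C   -0.1000  1.908  0.0860 sp2
atom CZ   C   -0.1000  1.908  0.0860 sp2
atom HD1  H    0.0600  1.387  0.0157 sp3
atom HD2  H    0.0600  1.387  0.0157 sp3
atom HE1  H    0.0600  1.387  0.0157 sp3
atom HE2  H    0.0600  1.387  0.0157 sp3
atom OH   O   -0.5500  1.661  0.2100 sp2
atom HH   H    0.3800  0.600  0.0157 sp3
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  110.5 -122.5
zmat CG   CB   CA   N     1.510  114.0 chi1
zmat HB2  CB   CA   N     1.090  109.0 chi1+121
zmat HB3  CB   CA   N     1.090  109.0 chi1-121
zmat CD1  CG   CB   CA    1.390  120.0 chi2
zmat CD2  CG   CB   CA    1.390  120.0 chi2+180
zmat CE1  CD1  CG   CB    1.390  120.0 180
zmat CE2  CD2  CG   CB    1.390  120.0 180
zmat CZ   CE1  CD1  CG    1.390  120.0 0
zmat HD1  CD1  CG   CB    1.080  120.0 0
zmat HD2  CD2  CG   CB    1.080  120.0 0
zmat HE1  CE1  CD1  CG    1.080  120.0 180
zmat HE2  CE2  CD2  CG    1.080  120.0 180
zmat OH   CZ   CE1  CD1   1.364  120.0 180
zmat HH   OH   CZ   CE1   0.960  109.0 180
bond CZ CE2 1.39
chi chi1 N CA CB CG
chi chi2 CA CB CG CD1
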