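code ARG
class natural
letter R
fullname arginine
formal_charge 1
chiral yes
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C    0.6944  1.908  0.0860 sp3
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
atom NE   N   -0.5000  1.824  0.1700 sp2
atom HD2  H    0.0600  1.387  0.0157 sp3
atom HD3  H    0.0600  1.387  0.0157 sp3
atom CZ   C   -0.1000  1.908  0.0860 sp2
atom HE   H    0.3800  0.600  0.0157 sp3
atom NH1  N   -0.5000  1.824  0.1700 sp2
atom NH2  N   -0.5000  1.824  0.1700 sp2
atom HH11 H    0.3800  0.600  0.0157 sp3
atom HH12 H    0.3800  0.600  0.0157 sp3
atom HH21 H    0.3800  0.600  0.0157 sp3
atom HH22 H    0.3800  0.600  0.0157 sp3
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  110.5 -122.5
zmat CG   CB   CA   N     1.526  114.0 chi1
zmat HB2  CB   CA   N     1.090  109.0 chi1+121
zmat HB3  CB   CA   N     1.090  109.0 chi1-121
zmat CD   CG   CB   CA    1.526  111.0 chi2
zmat HG2  CG   CB   CA    1.090  109.0 chi2+121
zmat HG3  CG   CB   CA    1.090  109.0 chi2-121
zmat NE   CD   CG   CB    1.470  112.0 chi3
zmat HD2  CD   CG   CB    1.090  109.0 chi3+121
zmat HD3  CD   CG   CB    1.090  109.0 chi3-121
zmat CZ   NE   CD   CG    1.330  124.0 chi4
zmat HE   NE   CD   CG    1.010  118.0 chi4+180
zmat NH1  CZ   NE   CD    1.330  120.0 0
zmat NH2  CZ   NE   CD    1.330  120.0 180
zmat HH11 NH1  CZ   NE    1.010  120.0 0
zmat HH12 NH1  CZ   NE    1.010  120.0 180
zmat HH21 NH2  CZ   NE    1.010  120.0 0
zmat HH22 NH2  CZ   NE    1.010  120.0 180
chi chi1 N CA CB CG
chi chi2 CA CB CG CD
chi chi3 CB CG CD NE
chi chi4 CG CD NE CZ
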