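code LYS
class natural
letter K
fullname lysine
formal_charge 1
chiral yes
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C    0.3344  1.908  0.0860 sp3
atom C    C    0.5973  1.908  0.0860 sp2
atom O    O   -0.5679  1.661  0.2100 sp2
atom HA   H    0.0600  1.387  0.0157 sp3
atom CB   C   -0.1000  1.908  0.0860 sp3
atom CG   C   -0.1000  1.908  0.0860 sp3
atom HB2  H    0.0600  1.387  0.0157 sp3
atom HB3  H    0.0600  1.387  0.0157 sp3
atom CD   C   -0.1000  1.908  0.0860 sp3
atom HG2  H    0.0600  1.387  0.0157 sp3
atom HG3  H    0.0600  1.387  0.0157 sp3
atom CE   C   -0.1000  1.908  0.0860 sp3
atom HD2  H    0.0600  1.387  0.0157 sp3
atom HD3  H    0.0600  1.387  0.0157 sp3
atom NZ   N   -0.5000  1.824  0.1700 sp3
atom HE2  H    0.0600  1.387  0.0157 sp3
atom HE3  H    0.0600  1.387  0.0157 sp3
atom HZ1  H    0.3800  0.600  0.0157 sp3
atom HZ2  H    0.3800  0.600  0.0157 sp3
atom HZ3  H    0.3800  0.600  0.0157 sp3
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  110.5 -122.5
zmat CG   CB   CA   N     1.526  114.0 chi1
zmat HB2  CB   CA   N     1.090  109.0 chi1+121
zmat HB3  CB   CA   N     1.090  109.0 chi1-121
zmat CD   CG   CB   CA    1.526  111.0 chi2
zmat HG2  CG   CB   CA    1.090  109.0 chi2+121
zmat HG3  CG   CB   CA    1.090  109.0 chi2-121
zmat CE   CD   CG   CB    1.526  111.0 chi3
zmat HD2  CD   CG   CB    1.090  109.0 chi3+121
zmat HD3  CD   CG   CB    1.090  109.0 chi3-121
zmat NZ   CE   CD   CG    1.470  111.0 chi4
zmat HE2  CE   CD   CG    1.090  109.0 chi4+121
zmat HE3  CE   CD   CG    1.090  109.0 chi4-121
zmat HZ1  NZ   CE   CD    1.010  109.5 60
zmat HZ2  NZ   CE   CD    1.010  109.5 180
zmat HZ3  NZ   CE   CD    1.010  109.5 -60
chi chi1 N CA CB CG
chi chi2 CA CB CG CD
chi chi3 CB CG CD CE
chi chi4 CG CD CE NZ
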