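code ILE
class natural
letter I
fullname isoleucine
formal_charge 0
chiral yes
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C   -0.0856  1.908  0.0860 sp3
atom C    C    0.5973  1.908  0.0860 sp2
atom O    O   -0.5679  1.661  0.2100 sp2
atom HA   H    0.0600  1.387  0.0157 sp3
atom CB   C   -0.1000  1.908  0.0860 sp3
atom CG1  C   -0.1000  1.908  0.0860 sp3
atom CG2  C   -0.1000  1.908  0.0860 sp3
atom HB   H    0.0600  1.387  0.0157 sp3
atom CD1  C   -0.1000  1.908  0.0860 sp3
atom HG12 H    0.0600  1.387  0.0157 sp3
atom HG13 H    0.0600  1.387  0.0157 sp3
atom HG21 H    0.0600  1.387  0.0157 sp3
atom HG22 H    0.0600  1.387  0.0157 sp3
atom HG23 H    0.0600  1.387  0.0157 sp3
atom HD11 H    0.0600  1.387  0.0157 sp3
atom HD12 H    0.0600  1.387  0.0157 sp3
atom HD13 H    0.0600  1.387  0.0157 sp3
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  110.5 -122.5
zmat CG1  CB   CA   N     1.526  110.5 chi1
zmat CG2  CB   CA   N     1.526  110.5 chi1-122
zmat HB   CB   CA   N     1.090  108.0 chi1+118
zmat CD1  CG1  CB   CA    1.526  110.5 chi2
zmat HG12 CG1  CB   CA    1.090  109.0 chi2+121
zmat HG13 CG1  CB   CA    1.090  109.0 chi2-121
zmat HG21 CG2  CB   CA    1.090  109.5 60
zmat HG22 CG2  CB   CA    1.090  109.5 180
zmat HG23 CG2  CB   CA    1.090  109.5 -60
zmat HD11 CD1  CG1  CB    1.090  109.5 60
zmat HD12 CD1  CG1  CB    1.090  109.5 180
zmat HD13 CD1  CG1  CB    1.090  109.5 -60
chi chi1 N CA CB CG1
chi chi2 CA CB CG1 CD1
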