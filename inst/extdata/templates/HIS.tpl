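code HIS
class natural
letter H
fullname histidine_(NE2-H_tautomer)
formal_charge 0
chiral yes
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C    0.8344  1.908  0.0860 sp3
atom C    C    0.5973  1.908  0.0860 sp2
atom O    O   -0.5679  1.661  0.2100 sp2
atom HA   H    0.0600  1.387  0.0157 sp3
atom CB   C   -0.1000  1.908  0.0860 sp3
atom CG   C   -0.1000  1.908  0.0860 sp2
atom HB2  H    0.0600  1.387  0.0157 sp3
atom HB3  H    0.0600  1.387  0.0157 sp3
atom ND1  N   -0.5000  1.824  0.1700 sp2
atom CD2  C   -0.1000  1.908  0.0860 sp2
atom CE1  C   -0.1000  1.908  0.0860 sp2
atom NE2  N   -0.5000  1.824  0.1700 sp2
atom HD2  H    0.0600  1.387  0.0157 sp3
atom HE1  H    0.0600  1.387  0.0157 sp3
atom HE2  H    0.3800  0.600  0.0157 sp3
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  110.5 -122.5
zmat CG   CB   CA   N     1.500  114.0 chi1
zmat HB2  CB   CA   N     1.090  109.0 chi1+121
zmat HB3  CB   CA   N     1.090  109.0 chi1-121
zmat ND1  CG   CB   CA    1.380  122.0 chi2
zmat CD2  CG   CB   CA    1.360  129.0 chi2+180
zmat CE1  ND1  CG   CB    1.320  105.0 180
zmat NE2  CD2  CG   CB    1.370  107.0 180
zmat HD2  CD2  CG   CB    1.080  126.0 0
zmat HE1  CE1  ND1  CG    1.080  126.0 180
zmat HE2  NE2  CD2  CG    1.010  126.0 180
bond CE1 NE2 1.32
chi chi1 N CA CB CG
chi chi2 CA CB CG ND1
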