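code MET
class natural
letter M
fullname methionine
formal_charge 0
chiral yes
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C    0.1844  1.908  0.0860 sp3
atom C    C    0.5973  1.908  0.0860 sp2
atom O    O   -0.5679  1.661  0.2100 sp2
atom HA   H    0.0600  1.387  0.0157 sp3
atom CB   C   -0.1000  1.908  0.0860 sp3
atom CG   C   -0.1000  1.908  0.0860 sp3
atom HB2  H    0.0600  1.387  0.0157 sp3
atom HB3  H    0.0600  1.387  0.0157 sp3
atom SD   S   -0.2500  2.000  0.2500 sp3
atom HG2  H    0.0600  1.387  0.0157 sp3
atom HG3  H    0.0600  1.387  0.0157 sp3
atom CE   C   -0.1000  1.908  0.0860 sp3
atom HE1  H    0.0600  1.387  0.0157 sp3
atom HE2  H    0.0600  1.387  0.0157 sp3
atom HE3  H    0.0600  1.387  0.0157 sp3
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  110.5 -122.5
zmat CG   CB   CA   N     1.526  114.0 chi1
zmat HB2  CB   CA   N     1.090  109.0 chi1+121
zmat HB3  CB   CA   N     1.090  109.0 chi1-121
zmat SD   CG   CB   CA    1.810  112.7 chi2
zmat HG2  CG   CB   CA    1.090  109.0 chi2+121
zmat HG3  CG   CB   CA    1.090  109.0 chi2-121
zmat CE   SD   CG   CB    1.790  100.9 chi3
zmat HE1  CE   SD   CG    1.090  109.5 60
zmat HE2  CE   SD   CG    1.090  109.5 180
zmat HE3  CE   SD   CG    1.090  109.5 -60
chi chi1 N CA CB CG
chi chi2 CA CB CG SD
chi chi3 CB CG SD CE
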