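code TRP
class natural
letter W
fullname tryptophan
formal_charge 0
chiral yes
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C    0.6544  1.908  0.0860 sp3
atom C    C    0.5973  1.908  0.0860 sp2
atom O    O   -0.5679  1.661  0.2100 sp2
atom HA   H    0.0600  1.387  0.0157 sp3
atom CB   C   -0.1000  1.908  0.0860 sp3
atom CG   C   -0.1000  1.908  0.0860 sp2
atom HB2  H    0.0600  1.387  0.0157 sp3
atom HB3  H    0.0600  1.387  0.0157 sp3
atom CD1  C   -0.1000  1.908  0.0860 sp2
atom CD2  C   -0.1000  1.908  0.0860 sp2
atom NE1  N   -0.5000  1.824  0.1700 sp2
atom CE2  C   -0.1000  1.908  0.0860 sp2
atom CE3  C   -0.1000  1.908  0.0860 sp2
atom CZ2  C   -0.1000  1.908  0.0860 sp2
atom CZ3  C   -0.1000  1.908  0.0860 sp2
atom CH2  C   -0.1000  1.908  0.0860 sp2
atom HD1  H    0.0600  1.387  0.0157 sp3
atom HE1  H    0.3800  0.600  0.0157 sp3
atom HE3  H    0.0600  1.387  0.0157 sp3
atom HZ2  H    0.0600  1.387  0.0157 sp3
atom HZ3  H    0.0600  1.387  0.0157 sp3
atom HH2  H    0.0600  1.387  0.0157 sp3
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  110.5 -122.5
zmat CG   CB   CA   N     1.510  114.0 chi1
zmat HB2  CB   CA   N     1.090  109.0 chi1+121
zmat HB3  CB   CA   N     1.090  109.0 chi1-121
zmat CD1  CG   CB   CA    1.370  127.0 chi2
zmat CD2  CG   CB   CA    1.430  126.0 chi2+180
zmat NE1  CD1  CG   CB    1.380  110.0 180
zmat CE2  NE1  CD1  CG    1.370  109.0 0
zmat CE3  CD2  CG   CB    1.400  134.0 0
zmat CZ2  CE2  CD2  CG    1.390  122.0 180
zmat CZ3  CE3  CD2  CG    1.390  118.0 180
zmat CH2  CZ2  CE2  CD2   1.370  117.0 0
zmat HD1  CD1  CG   CB    1.080  126.0 0
zmat HE1  NE1  CD1  CG    1.010  125.0 180
zmat HE3  CE3  CD2  CG    1.080  120.0 0
zmat HZ2  CZ2  CE2  CD2   1.080  120.0 180
zmat HZ3  CZ3  CE3  CD2   1.080  120.0 180
zmat HH2  CH2  CZ2  CE2   1.080  120.0 180
bond CE2 CD2 1.4
bond CH2 CZ3 1.4
chi chi1 N CA CB CG
chi chi2 CA CB CG CD1
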