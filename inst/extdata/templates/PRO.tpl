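code PRO
class natural
letter P
fullname proline
formal_charge 0
chiral yes
amide_h no
atom N    N   -0.4157  1.824  0.1700 sp2
atom CA   C    0.2663  1.908  0.0860 sp3
atom C    C    0.5973  1.908  0.0860 sp2
atom O    O   -0.5679  1.661  0.2100 sp2
atom HA   H    0.0600  1.387  0.0157 sp3
atom CB   C   -0.1000  1.908  0.0860 sp3
atom CG   C   -0.1000  1.908  0.0860 sp3
atom CD   C   -0.1000  1.908  0.0860 sp3
atom HB2  H    0.0600  1.387  0.0157 sp3
atom HB3  H    0.0600  1.387  0.0157 sp3
atom HG2  H    0.0600  1.387  0.0157 sp3
atom HG3  H    0.0600  1.387  0.0157 sp3
atom HD2  H    0.0600  1.387  0.0157 sp3
atom HD3  H    0.0600  1.387  0.0157 sp3
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  103.0 -120
zmat CG   CB   CA   N     1.526  104.0 30
zmat CD   CG   CB   CA    1.526  105.0 -35
zmat HB2  CB   CA   N     1.090  110.0 151
zmat HB3  CB   CA   N     1.090  110.0 -91
zmat HG2  CG   CB   CA    1.090  110.0 86
zmat HG3  CG   CB   CA    1.090  110.0 -156
zmat HD2  CD   CG   CB    1.090  110.0 146
zmat HD3  CD   CG   CB    1.090  110.0 -96
bond CD N 1.473
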