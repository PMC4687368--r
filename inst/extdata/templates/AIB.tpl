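code AIB
class nonnatural
letter X
fullname 2-aminoisobutyric_acid_(synthetic_template)
formal_charge 0
chiral no
amide_h yes
atom N    N   -0.4157  1.824  0.1700 sp2
atom H    H    0.2719  0.600  0.0157 sp3
atom CA   C   -0.0456  1.908  0.0860 sp3
atom C    C    0.5973  1.908  0.0860 sp2
atom O    O   -0.5679  1.661  0.2100 sp2
atom CB1  C   -0.1000  1.908  0.0860 sp3
atom CB2  C   -0.1000  1.908  0.0860 sp3
atom HB11 H    0.0600  1.387  0.0157 sp3
atom HB12 H    0.0600  1.387  0.0157 sp3
atom HB13 H    0.0600  1.387  0.0157 sp3
atom HB21 H    0.0600  1.387  0.0157 sp3
atom HB22 H    0.0600  1.387  0.0157 sp3
atom HB23 H    0.0600  1.387  0.0157 sp3
zmat CB1  CA   N    C     1.526  110.5 -122.5
zmat CB2  CA   N    C     1.526  110.5 119
zmat HB11 CB1  CA   N     1.090  109.5 60
zmat HB12 CB1  CA   N     1.090  109.5 180
zmat HB13 CB1  CA   N     1.090  109.5 -60
zmat HB21 CB2  CA   N     1.090  109.5 60
zmat HB22 CB2  CA   N     1.090  109.5 180
zmat HB23 CB2  CA   N     1.090  109.5 -60
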