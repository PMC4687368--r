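code THR
class natural
letter T
fullname threonine
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
atom OG1  O   -0.5500  1.661  0.2100 sp3
atom CG2  C   -0.1000  1.908  0.0860 sp3
atom HB   H    0.0600  1.387  0.0157 sp3
atom HG1  H    0.3800  0.600  0.0157 sp3
atom HG21 H    0.0600  1.387  0.0157 sp3
atom HG22 H    0.0600  1.387  0.0157 sp3
atom HG23 H    0.0600  1.387  0.0157 sp3
zmat HA   CA   N    C     1.090  108.5 119
zmat CB   CA   N    C     1.526  110.5 -122.5
zmat OG1  CB   CA   N     1.417  109.5 chi1
zmat CG2  CB   CA   N     1.526  110.5 chi1-122
zmat HB   CB   CA   N     1.090  108.0 chi1+118
zmat HG1  OG1  CB   CA    0.960  108.5 180
zmat HG21 CG2  CB   CA    1.090  109.5 60
zmat HG22 CG2  CB   CA    1.090  109.5 180
zmat HG23 CG2  CB   CA    1.090  109.5 -60
chi chi1 N CA CB OG1
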