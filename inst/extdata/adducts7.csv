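"label","kind","delta"
"M+H-2H2O","adduct",-35.01330433541
"M+H-H2O","adduct",-17.00273965167
"M+NH4-H2O","adduct",0.0238094493399998
"M+Li","adduct",7.01600455
"M+NH4","adduct",18.03437413308
"M+CH3OH-H","adduct",31.01838971581
"M+K","adduct",38.96370668
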