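"label","kind","delta"
"M+CH3","biotransformation",15.02347509621
"M+C6H12O6","biotransformation",180.06338810244
"M+OH","biotransformation",17.00273965167
"M+COOH","biotransformation",44.99765427127
"M+NH2","biotransformation",16.01872406894
"M+NH3","biotransformation",17.02654910101
"M-H+OH","biotransformation",15.9949146196
"M-H+2OH","biotransformation",32.99765427127
"M-H+NH2","biotransformation",15.01089903687
"M-CH3+H","biotransformation",-14.01565006414
"M-CH3+OH","biotransformation",1.97926455546
"M-CH3+NH2","biotransformation",0.99524897273
"M-C6H12O6+H","biotransformation",-179.05556307037
"M-C6H12O6+OH","biotransformation",-163.06064845077
"M-C6H12O6+NH2","biotransformation",-164.0446640335
"M-C6H12O6+CH3","biotransformation",-165.03991300623
"M-OH+H2","biotransformation",-14.98708958753
"M-OH+CH3","biotransformation",-1.97926455546
"M-OH+C6H12O6","biotransformation",163.06064845077
"M-OH+COOH","biotransformation",27.9949146196
"M-OH+NH2","biotransformation",-0.984015582729999
"M-OH+NH3","biotransformation",0.0238094493400034
"M-NH2+H2","biotransformation",-14.0030740048
"M-NH2+CH3","biotransformation",-0.99524897273
"M-NH2+C6H12O6","biotransformation",164.0446640335
"M-NH2+COOH","biotransformation",28.97893020233
"M-NH2+OH","biotransformation",0.984015582729999
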