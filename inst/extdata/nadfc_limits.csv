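analyte,limit_mg_kg
ACE,600
BEN,600
SOR,1000
SAC,120
TAR,300
CAF,250
SUN,300
ASP,600
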