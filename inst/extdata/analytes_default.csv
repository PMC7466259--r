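name,log_kw_neutral,log_kw_ionized,S,pKa,acid_or_base,plate_count
ACE,1.30,0.70,3.2,5.0,acid,9000
BEN,1.55,0.95,3.2,5.6,acid,10000
SOR,1.80,1.20,3.3,6.0,acid,10000
SAC,1.85,1.25,3.3,5.2,acid,11000
TAR,2.18,1.58,3.4,6.3,acid,10000
CAF,2.28,2.28,3.4,NA,neutral,12000
SUN,2.52,1.92,3.5,6.0,acid,10000
ASP,2.72,2.12,3.5,6.5,acid,9000
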