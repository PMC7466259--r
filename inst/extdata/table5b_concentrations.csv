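sample,analyte,concentration,sd
01,ACE,181.97,0.45
01,TAR,61.72,0.14
01,SUN,5.33,0.44
01,ASP,446.96,0.44
02,ACE,140.86,0.56
02,TAR,18.80,0.13
02,SUN,8.11,0.01
02,ASP,495.24,0.38
03,ACE,185.71,0.72
03,TAR,12.77,0.06
03,ASP,156.75,0.14
04,BEN,77.87,0.53
04,SOR,42.50,0.13
04,SAC,117.97,0.45
04,ASP,476.01,0.85
05,ACE,204.68,0.87
05,TAR,15.66,0.15
05,ASP,163.25,0.28
06,ACE,491.17,0.72
06,TAR,12.04,0.32
06,CAF,31.45,0.20
06,ASP,188.11,0.96
07,CAF,94.62,0.46
07,ASP,274.82,0.17
08,ACE,70.68,0.50
08,CAF,66.17,0.64
08,ASP,437.57,0.27
09,ACE,173.10,0.73
09,TAR,10.51,0.06
09,CAF,22.06,0.38
09,ASP,258.76,0.62
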