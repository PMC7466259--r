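term,Rs1-2,Rs2-3,Rs3-4,Rs4-5,Rs5-6,Rs6-7,Rs7-8,time
x1,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE
x2,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE
x3,FALSE,TRUE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE
x1x1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
x1x2,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
x1x3,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
x2x2,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
x2x3,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
x3x3,TRUE,TRUE,FALSE,TRUE,TRUE,TRUE,FALSE,FALSE
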