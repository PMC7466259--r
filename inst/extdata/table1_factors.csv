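name,low,high,units
%B initial,0,10,%
%B end,60,100,%
pH,3,7,pH
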