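wave,u5mr,u5mr_lo,u5mr_hi,nmr
1993-1994,128,NA,NA,53
1996-1997,110,NA,NA,49
2004,70,NA,NA,36
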