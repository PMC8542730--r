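cluster,deaths_bb,n_bb,deaths_placebo,n_placebo
SRall,907,6546,1121,6276
SR1,8,211,14,222
SR2,34,514,40,487
SR3,59,683,108,731
SR4,140,1306,151,1231
SR5,202,1791,267,1706
SR6,464,2041,541,1899
AFall,278,1412,300,1425
AF1,59,301,50,307
AF2,29,321,50,338
AF3,69,348,68,348
AF4,68,202,81,201
AF5,53,240,51,231
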