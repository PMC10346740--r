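date,sheep,true,pred_peak,pred_behavior
Sep-03,Ram1,147,154,155
Sep-03,Ram1,125,131,132
Sep-05,Ewe1,100,93,93
Sep-05,Ewe1,82,158,101
Sep-06,Ram2,78,88,80
Sep-06,Ram2,219,229,217
Sep-07,Ewe2,243,238,238
Sep-07,Ewe2,187,165,193
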