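date,run_true,run_pred_peak,run_pred_behavior,shake_detections,shake_errors
Sep-03,56,43,60,5,1
Sep-05,9,8,9,25,2
Sep-06,81,65,78,12,1
Sep-07,83,63,98,1,1
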