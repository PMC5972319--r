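{"A":[[0.23,6.43,-9.7],[-4.97,4.73,-3.59],[-36.78,30.81,-87.24]],"constant":605.15,"feature_order":["hr_before","hr_during","hr_after","hf_before","hf_during","hf_after","lfhf_before","lfhf_during","lfhf_after"],"orientation":"healthy_high"}
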