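region,subregion,stressed_mean,stressed_sd,control_mean,control_sd,p_printed
CA1,SO,0.27,0.03,0.40,0.10,0.03
CA1,CL,0.24,0.05,0.33,0.05,0.11
CA1,SR,0.26,0.02,0.39,0.06,0.03
CA1,LM,0.31,0.05,0.41,0.04,0.06
CA3,SO,0.36,0.06,0.41,0.12,0.69
CA3,CL,0.30,0.03,0.32,0.06,0.69
CA3,SR,0.33,0.03,0.43,0.07,0.03
CA3,LM,0.31,0.03,0.41,0.05,0.03
DG,GL,0.23,0.005,0.31,0.04,0.03
DG,ML,0.28,0.03,0.36,0.03,0.03
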