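variant,temperature_K,KD1_uM,KD1_sd,KD2_uM,KD2_sd,KD3_uM,KD3_sd,R2_worst,chi2_worst
WT,293,0.51,0.04,1.16,0.07,,,0.97,0.08
WT,298,0.44,0.02,0.93,0.09,,,0.94,0.17
WT,303,0.38,0.02,0.73,0.05,,,0.94,0.15
WT,310,0.31,0.01,0.53,0.04,,,0.92,0.2
R188A,293,1.56,0.09,3.46,0.15,10.98,1.15,0.98,0.07
R188A,298,1.53,0.11,3.40,0.21,10.15,1.62,0.98,0.06
R188A,303,1.35,0.10,2.90,0.26,9.02,1.11,0.98,0.05
R188A,310,0.93,0.09,1.89,0.24,5.50,1.10,0.97,0.07
R238A,293,1.67,0.23,6.71,1.38,,,0.99,0.05
R238A,298,0.91,0.10,3.15,0.12,,,0.98,0.06
R238A,303,0.34,0.04,1.09,0.23,3.75,0.60,0.95,0.11
R238A,310,0.10,0.02,0.33,0.11,0.92,0.38,1,0
K243A,293,2.01,0.06,5.26,0.85,,,0.99,0.02
K243A,298,1.46,0.01,3.90,0.48,,,0.99,0.03
K243A,303,0.60,0.02,1.54,0.12,3.72,0.54,0.98,0.04
K243A,310,0.25,0.02,0.46,0.02,1.06,0.04,0.89,0.2
R188A R238A,293,1.24,0.10,4.82,0.16,,,0.99,0.03
R188A R238A,298,1.17,0.11,4.65,0.92,,,0.99,0.02
R188A R238A,303,0.87,0.06,3.05,0.26,,,0.98,0.04
R188A R238A,310,0.39,0.05,1.28,0.09,6.36,1.07,0.98,0.04
R188A K243A,293,3.64,0.28,15.66,4.76,,,0.99,0.03
R188A K243A,298,2.23,0.07,6.68,0.17,,,0.99,0.03
R188A K243A,303,1.06,0.05,3.10,0.33,19.33,3.70,0.99,0.03
R188A K243A,310,0.66,0.02,1.56,0.04,5.70,0.93,0.98,0.04
R238A K243A,293,1.31,0.04,4.35,0.07,,,0.99,0.03
R238A K243A,298,1.03,0.09,3.65,0.15,,,0.99,0.02
R238A K243A,303,0.48,0.05,1.97,0.09,,,0.97,0.09
R238A K243A,310,0.10,0.02,0.58,0.06,,,0.74,0.93
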