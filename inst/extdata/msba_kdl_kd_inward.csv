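variant,temperature_K,KD1_uM,KD1_sd,KD2_uM,KD2_sd,KD3_uM,KD3_sd,R2_worst,chi2_worst
WT,288,0.69,0.06,2.64,0.16,6.60,0.54,0.99,0.01
WT,293,0.75,0.04,2.86,0.23,6.94,0.56,0.99,0.01
WT,298,0.68,0.05,2.53,0.17,6.01,0.40,0.99,0.01
WT,303,0.43,0.05,1.36,0.10,3.30,0.23,0.96,0.06
R78A,288,1.91,0.17,6.18,0.80,,,0.98,0.04
R78A,293,1.87,0.18,6.18,0.37,,,0.98,0.05
R78A,298,2.00,0.20,5.23,0.47,,,0.98,0.04
R78A,303,7.68,0.47,5.72,0.21,,,1,0
R188A,288,2.21,0.17,11.01,1.95,,,0.99,0.03
R188A,293,2.28,0.12,11.62,2.17,,,0.99,0.03
R188A,298,1.98,0.07,8.92,0.73,,,0.99,0.03
R188A,303,1.32,0.05,4.37,0.13,,,0.95,0.12
R238A,288,2.48,0.12,4.74,0.45,,,0.99,0.02
R238A,293,3.55,0.10,6.21,0.40,,,1,0.01
R238A,298,4.70,0.07,9.66,0.82,,,1,0.01
R238A,303,4.71,0.20,9.94,0.40,,,1,0.02
K243A,288,1.24,0.07,7.28,0.78,,,0.99,0.03
K243A,293,1.41,0.09,7.38,0.53,,,0.99,0.02
K243A,298,1.28,0.05,6.65,0.50,,,0.99,0.02
K243A,303,0.74,0.07,3.73,0.32,,,0.97,0.06
K299A,288,2.32,0.06,6.07,0.33,17.54,6.77,1,0.01
K299A,293,2.35,0.07,5.75,0.07,16.03,3.18,0.99,0.02
K299A,298,2.12,0.09,5.07,0.12,14.01,1.59,0.99,0.02
K299A,303,1.38,0.01,2.91,0.02,5.91,0.55,0.97,0.05
R78A K299A,288,2.56,0.17,7.77,0.11,,,0.98,0.06
R78A K299A,293,3.08,0.13,8.92,0.39,,,0.99,0.03
R78A K299A,298,3.17,0.17,6.78,0.82,,,0.99,0.02
R78A K299A,303,6.91,0.66,11.96,2.83,,,0.99,0.03
R188A R238A,288,5.55,0.87,,,,,0.99,0.02
R188A R238A,293,8.51,0.67,,,,,1,0.01
R188A R238A,298,13.01,0.43,,,,,1,0
R188A R238A,303,11.14,0.23,,,,,1,0
R188A K243A,288,1.06,0.02,5.84,0.29,,,0.99,0.01
R188A K243A,293,1.07,0.02,6.07,0.13,,,0.99,0.01
R188A K243A,298,1.05,0.02,5.82,0.06,,,0.99,0.02
R188A K243A,303,0.75,0.01,4.35,0.17,,,0.99,0.03
R188A K299A,288,13.86,0.85,13.83,3.23,,,0.99,0.04
R188A K299A,293,12.55,0.64,14.29,2.18,,,0.99,0.03
R188A K299A,298,9.82,0.70,11.50,1.04,,,0.98,0.05
R188A K299A,303,4.86,0.44,8.56,0.20,,,0.99,0.04
R238A K243A,288,2.79,0.20,7.93,0.47,,,0.98,0.06
R238A K243A,293,3.26,0.09,7.39,0.50,,,0.99,0.03
R238A K243A,298,6.53,0.2,8.97,0.15,,,1,0
R238A K243A,303,7.63,0.26,10.78,2.19,,,1,0.01
R188A R238A K243A,288,20.53,2.25,,,,,1,0
R188A R238A K243A,293,21.09,2.84,,,,,1,0
R188A R238A K243A,298,19.80,1.71,,,,,1,0
R188A R238A K243A,303,13.12,0.81,,,,,1,0
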