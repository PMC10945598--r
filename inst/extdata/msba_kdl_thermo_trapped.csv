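variant,temperature_K,event,dG_kJmol,dG_sd,dH_kJmol,dH_sd,mTdS_kJmol,mTdS_sd,dCp_kJmolK,dCp_sd
WT,293,1,-35.3,0.1,21.9,1.5,-57.2,1.3,,
WT,293,2,-33.3,0.2,35.0,0.6,-68.3,0.6,,
WT,298,1,-36.3,0.1,21.9,1.5,-58.2,1.3,,
WT,298,2,-34.4,0.2,35.0,0.6,-69.4,0.6,,
WT,303,1,-37.3,0.1,21.9,1.5,-59.2,1.3,,
WT,303,2,-35.6,0.2,35.0,0.6,-70.6,0.6,,
WT,310,1,-38.6,0.1,21.9,1.5,-60.5,1.3,,
WT,310,2,-37.2,0.2,35.0,0.6,-72.2,0.6,,
R188A,293,1,-32.6,0.1,-6.6,2.6,-26.0,2.7,3.6,0.1
R188A,293,2,-30.7,0.1,-7.2,2.4,-23.4,2.5,4.1,0.2
R188A,293,3,-27.8,0.3,-3.2,21.3,-24.7,21.1,4.1,2.7
R188A,298,1,-33.2,0.2,11.3,2.6,-44.5,2.7,3.5,0.1
R188A,298,2,-31.2,0.1,13.4,3.3,-44.7,3.4,4.2,0.3
R188A,298,3,-28.5,0.4,17.6,12.4,-46.1,12.3,3.6,4.2
R188A,303,1,-34.1,0.2,29.2,2.5,-63.3,2.6,3.6,0.1
R188A,303,2,-32.2,0.2,34.1,4.3,-66.3,4.5,4.1,0.2
R188A,303,3,-29.3,0.3,37.8,14.8,-67.1,15.1,4.9,1.4
R188A,310,1,-35.8,0.2,54.3,2.6,-90.2,2.8,3.6,0.1
R188A,310,2,-34.0,0.3,63.0,5.8,-97.0,6.1,4.1,0.2
R188A,310,3,-31.3,0.5,67.9,26.1,-99.2,26.6,4.3,2.2
R238A,293,1,-32.1,0.2,126.8,5.8,-158.9,5.9,,
R238A,293,2,-28.9,0.4,137.7,10.8,-166.5,10.8,,
R238A,298,1,-34.8,0.4,126.8,5.8,-161.6,6.0,,
R238A,298,2,-31.7,0.4,137.7,10.8,-169.4,11.0,,
R238A,303,1,-37.6,0.4,126.8,5.8,-164.3,6.1,,
R238A,303,2,-34.6,0.5,137.7,10.8,-172.2,11.1,,
R238A,310,1,-41.4,0.5,126.8,5.8,-168.1,6.2,,
R238A,310,2,-38.5,0.7,137.7,10.8,-176.2,11.4,,
K243A,293,1,-31.6,0.1,96.2,5.1,-127.9,5.1,,
K243A,293,2,-29.1,0.2,111.7,6.9,-140.8,6.6,,
K243A,298,1,-33.8,0.1,96.2,5.1,-130.0,5.1,,
K243A,298,2,-31.5,0.1,111.7,6.9,-143.2,6.7,,
K243A,303,1,-36.0,0.1,96.2,5.1,-132.2,5.3,,
K243A,303,2,-33.9,0.1,111.7,6.9,-145.6,6.9,,
K243A,310,1,-39.1,0.2,96.2,5.1,-135.3,5.4,,
K243A,310,2,-37.3,0.2,111.7,6.9,-149.0,7.1,,
R188A R238A,293,1,-33.2,0.2,-10.2,3.0,-23.0,3.1,7.5,1.0
R188A R238A,293,2,-29.8,0.1,-8.2,30.4,-21.7,30.3,8.1,3.5
R188A R238A,298,1,-33.9,0.2,27.2,2.5,-61.0,2.6,7.5,0.3
R188A R238A,298,2,-30.5,0.5,31.9,13.7,-62.4,14.2,8.6,4.6
R188A R238A,303,1,-35.2,0.2,64.5,7.3,-99.7,7.2,7.5,2.1
R188A R238A,303,2,-32.0,0.2,72.5,4.9,-104.5,4.8,7.4,1.9
R188A R238A,310,1,-38.1,0.4,116.9,16.4,-155.0,16.8,7.5,1.3
R188A R238A,310,2,-35.0,0.2,127.7,25.9,-162.7,25.9,7.9,3.0
R188A K243A,293,1,-30.5,0.2,92.4,8.6,-122.9,8.4,-1.8,0.9
R188A K243A,293,2,-27.0,0.7,135.4,44.8,-162.4,44.1,-4.0,4.0
R188A K243A,298,1,-32.3,0.1,82.1,4.4,-114.4,4.3,-0.1,0.9
R188A K243A,298,2,-29.5,0.1,114.7,25.2,-144.2,25.2,-3.4,4.5
R188A K243A,303,1,-34.7,0.1,73.4,0.1,-108.0,0.1,-4.4,0.8
R188A K243A,303,2,-32.0,0.3,94.5,5.7,-126.5,5.6,-4.9,3.8
R188A K243A,310,1,-36.7,0.1,55.6,5.7,-92.3,5.7,-2.6,0.8
R188A K243A,310,2,-34.5,0.1,64.4,22.9,-98.9,22.9,-4.3,3.9
R238A K243A,293,1,-33.0,0.1,8.9,14.2,-41.9,14.2,12.7,2.7
R238A K243A,293,2,-30.1,0.1,6.5,2.2,-36.6,2.1,10.0,0.7
R238A K243A,298,1,-34.2,0.2,71.8,7.2,-106.0,7.4,13.2,2.1
R238A K243A,298,2,-31.0,0.1,56.1,2.1,-87.1,2.2,10.5,0.9
R238A K243A,303,1,-36.7,0.2,135.3,16.2,-171.9,16.3,11.9,3.5
R238A K243A,303,2,-33.1,0.1,106.2,5.4,-139.3,5.5,9.1,1.0
R238A K243A,310,1,-41.6,0.8,222.4,35.8,-264.0,36.5,12.4,2.9
R238A K243A,310,2,-37.0,0.3,174.4,10.5,-211.4,10.8,9.7,0.7
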