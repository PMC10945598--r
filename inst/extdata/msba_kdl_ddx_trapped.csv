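event,background,variant,temperature_K,ddG,ddG_sd,ddH,ddH_sd,ddmTdS,ddmTdS_sd
1,WT,R188A,293,2.7,0.1,-28.5,3.1,31.2,3.1
1,WT,R188A,298,3.1,0.2,-10.6,2.9,13.7,3.1
1,WT,R188A,303,3.2,0.2,7.3,2.9,-4.1,2.9
1,WT,R188A,310,2.8,0.2,32.4,2.9,-29.7,3.1
1,WT,R238A,293,3.2,0.2,104.9,6.0,-101.7,6.0
1,WT,R238A,298,1.5,0.4,104.9,6.0,-103.4,6.1
1,WT,R238A,303,-0.3,0.4,104.9,6.0,-105.1,6.2
1,WT,R238A,310,-2.8,0.5,104.9,6.0,-107.6,6.4
1,WT,K243A,293,3.7,0.1,74.3,5.4,-70.7,5.3
1,WT,K243A,298,2.5,0.1,74.3,5.4,-71.8,5.3
1,WT,K243A,303,1.3,0.1,74.3,5.4,-73.0,5.4
1,WT,K243A,310,-0.5,0.2,74.3,5.4,-74.8,5.5
1,WT,R188A R238A,293,2.2,0.2,-32.1,3.3,34.2,3.4
1,WT,R188A R238A,298,2.4,0.2,5.3,2.9,-2.8,2.9
1,WT,R188A R238A,303,2.1,0.2,42.6,7.5,-40.5,7.3
1,WT,R188A R238A,310,0.5,0.4,95.0,16.5,-94.5,16.8
1,WT,R188A K243A,293,4.8,0.2,70.5,8.7,-65.7,8.6
1,WT,R188A K243A,298,4.0,0.1,60.2,4.7,-56.2,4.5
1,WT,R188A K243A,303,2.6,0.1,51.5,1.5,-48.8,1.3
1,WT,R188A K243A,310,1.9,0.1,33.7,5.9,-31.8,5.9
1,WT,R238A K243A,293,2.3,0.1,-13.0,14.3,15.3,14.2
1,WT,R238A K243A,298,2.1,0.2,49.9,7.3,-47.8,7.6
1,WT,R238A K243A,303,0.6,0.2,113.4,16.3,-112.7,16.4
1,WT,R238A K243A,310,-3.0,0.9,200.5,35.8,-203.5,36.5
2,WT,R188A,293,2.7,0.2,-42.2,2.4,44.9,2.6
2,WT,R188A,298,3.2,0.2,-21.6,3.3,24.8,3.4
2,WT,R188A,303,3.5,0.4,-0.9,4.4,4.3,4.5
2,WT,R188A,310,3.2,0.4,28.0,5.9,-24.8,6.1
2,WT,R238A,293,4.4,0.5,102.7,10.8,-98.2,10.8
2,WT,R238A,298,2.7,0.5,102.7,10.8,-100.0,11.0
2,WT,R238A,303,1.0,0.5,102.7,10.8,-101.6,11.1
2,WT,R238A,310,-1.3,0.7,102.7,10.8,-104.0,11.4
2,WT,K243A,293,4.2,0.4,76.7,6.9,-72.5,6.6
2,WT,K243A,298,2.9,0.2,76.7,6.9,-73.8,6.7
2,WT,K243A,303,1.7,0.2,76.7,6.9,-75.0,6.9
2,WT,K243A,310,-0.1,0.4,76.7,6.9,-76.8,7.1
2,WT,R188A R238A,293,3.5,0.2,-43.2,30.4,46.7,30.3
2,WT,R188A R238A,298,3.9,0.5,-3.1,13.7,7.0,14.2
2,WT,R188A R238A,303,3.6,0.4,37.5,4.9,-33.9,4.8
2,WT,R188A R238A,310,2.2,0.2,92.7,25.8,-90.5,25.8
2,WT,R188A K243A,293,6.3,0.7,100.4,44.8,-94.1,44.1
2,WT,R188A K243A,298,4.9,0.2,79.7,25.2,-74.8,25.2
2,WT,R188A K243A,303,3.6,0.4,59.5,5.8,-55.9,5.6
2,WT,R188A K243A,310,2.7,0.2,29.4,22.9,-26.7,22.9
2,WT,R238A K243A,293,3.2,0.2,-28.5,2.2,31.7,2.2
2,WT,R238A K243A,298,3.4,0.2,21.1,2.2,-17.7,2.3
2,WT,R238A K243A,303,2.5,0.2,71.2,5.4,-68.7,5.5
2,WT,R238A K243A,310,0.2,0.4,139.4,10.5,-139.2,10.8
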