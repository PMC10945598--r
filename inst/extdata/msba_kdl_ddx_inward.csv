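event,background,variant,temperature_K,ddG,ddG_sd,ddH,ddH_sd,ddmTdS,ddmTdS_sd
1,WT,R78A,288,2.4,0.2,45.6,12.5,-43.2,12.4
1,WT,R78A,293,2.2,0.2,-7.8,7.5,10.0,7.5
1,WT,R78A,298,2.7,0.2,-61.7,11.3,64.4,11.3
1,WT,R188A,288,2.8,0.2,13.0,14.2,-10.2,14.0
1,WT,R188A,293,2.7,0.1,5.2,6.5,-2.5,6.5
1,WT,R188A,298,2.7,0.2,-3.0,6.9,5.6,7.0
1,WT,R188A,303,2.9,0.4,-11.2,14.7,14.1,14.9
1,WT,R238A,288,3.1,0.2,-30.9,12.1,33.9,11.9
1,WT,R238A,293,3.8,0.1,-46.9,6.7,50.7,6.7
1,WT,R238A,298,4.8,0.1,-62.9,7.5,67.7,7.6
1,WT,R238A,303,6.1,0.4,-78.8,13.5,84.9,13.7
1,WT,K243A,288,1.4,0.2,-12.5,13.7,13.9,13.5
1,WT,K243A,293,1.5,0.2,-2.7,6.5,4.3,6.5
1,WT,K243A,298,1.6,0.2,7.2,7.0,-5.6,7.1
1,WT,K243A,303,1.4,0.4,17.3,14.5,-15.9,14.8
1,WT,K299A,288,2.9,0.2,13.8,15.1,-10.9,14.8
1,WT,K299A,293,2.8,0.1,5.7,6.6,-2.9,6.7
1,WT,K299A,298,2.8,0.2,-2.4,6.1,5.2,6.2
1,WT,K299A,303,3.0,0.4,-10.3,14.3,13.3,14.6
1,WT,R78A K299A,288,3.2,0.2,-0.8,12.9,4.0,12.6
1,WT,R78A K299A,293,3.4,0.1,-19.2,6.1,22.7,6.1
1,WT,R78A K299A,298,3.8,0.2,-38.2,6.9,42.0,7.1
1,WT,R188A R238A,288,5.0,0.5,-57.4,19.1,62.4,18.7
1,WT,R188A R238A,293,5.9,0.2,-57.5,10.7,63.5,10.5
1,WT,R188A R238A,298,7.3,0.2,-56.6,7.5,64.0,7.5
1,WT,R188A R238A,303,8.2,0.4,-55.1,13.5,63.4,13.7
1,WT,R188A K243A,288,1.0,0.2,15.7,13.1,-14.6,12.9
1,WT,R188A K243A,293,0.9,0.1,0.3,6.2,0.6,6.2
1,WT,R188A K243A,298,1.1,0.2,-14.9,6.0,16.0,6.2
1,WT,R188A K243A,303,1.4,0.4,-29.9,12.7,31.4,13.0
1,WT,R188A K299A,288,7.2,0.2,20.6,20.0,-13.4,19.7
1,WT,R188A K299A,293,6.9,0.1,25.2,7.5,-18.3,7.5
1,WT,R188A K299A,298,6.6,0.2,30.2,9.6,-23.6,9.6
1,WT,R188A K299A,303,6.1,0.4,35.3,23.3,-29.2,23.5
1,WT,R238A K243A,288,3.4,0.2,-6.4,14.3,9.8,14.1
1,WT,R238A K243A,293,3.6,0.1,-51.1,8.1,54.7,8.1
1,WT,R238A K243A,298,5.6,0.2,-93.4,7.0,99.0,7.2
1,WT,R238A K243A,303,7.3,0.4,-134.4,12.5,141.6,12.9
1,R188A,R238A,288,2.2,0.2,-70.4,8.9,72.6,8.7
1,R188A,R238A,293,3.2,0.1,-62.7,5.4,65.9,5.3
1,R188A,R238A,298,4.7,0.1,-53.7,6.1,58.3,6.1
1,R188A,R238A,303,5.4,0.1,-43.9,10.2,49.3,10.3
1,R188A,K243A,288,-1.8,0.2,2.6,11.0,19.9,10.8
1,R188A,K243A,293,-1.8,0.2,-4.9,5.0,-6.4,5.0
1,R188A,K243A,298,-1.6,0.1,-11.9,5.4,10.4,5.4
1,R188A,K243A,303,-1.4,0.2,-18.7,11.5,17.3,11.8
1,R188A,R238A K243A,288,5.3,0.4,-2.2,10.0,7.5,9.7
1,R188A,R238A K243A,293,5.4,0.4,-2.9,5.1,8.4,4.9
1,R188A,R238A K243A,298,5.7,0.2,-3.2,3.8,8.9,3.7
1,R188A,R238A K243A,303,5.8,0.2,-3.2,8.9,9.0,8.9
1,R238A,R188A,288,1.9,0.2,-26.5,8.9,28.4,8.7
1,R238A,R188A,293,2.1,0.1,-10.6,5.4,12.8,5.3
1,R238A,R188A,298,2.5,0.1,6.3,6.1,-3.7,6.1
1,R238A,R188A,303,2.2,0.1,23.7,10.2,-21.5,10.3
1,R238A,K243A,288,0.3,0.2,24.4,8.0,-24.1,7.8
1,R238A,K243A,293,-0.2,0.1,-4.2,5.3,4.0,5.3
1,R238A,K243A,298,0.8,0.1,-30.5,6.2,31.3,6.2
1,R238A,K243A,303,1.2,0.2,-55.5,9.9,56.7,10.2
1,R238A,R188A K243A,288,5.1,0.2,41.7,6.6,-36.6,6.4
1,R238A,R188A K243A,293,4.3,0.4,49.1,5.4,-44.8,5.1
1,R238A,R188A K243A,298,3.6,0.2,56.7,4.9,-53.2,4.9
1,R238A,R188A K243A,303,2.6,0.2,64.5,6.7,-61.9,6.9
1,K243A,R188A,288,-0.4,0.2,28.1,11.0,-28.5,10.8
1,K243A,R188A,293,-0.7,0.2,3.0,5.0,-3.7,5.0
1,K243A,R188A,298,-0.5,0.1,-22.1,5.4,21.6,5.4
1,K243A,R188A,303,0.1,0.2,-47.2,11.5,47.3,11.8
1,K243A,R238A,288,1.9,0.2,6.1,8.0,-4.1,7.8
1,K243A,R238A,293,2.0,0.1,-48.4,5.3,50.4,5.3
1,K243A,R238A,298,4.0,0.1,-100.6,6.2,104.6,6.2
1,K243A,R238A,303,5.9,0.2,-151.6,9.9,157.5,10.2
1,K243A,R188A R238A,288,6.7,0.2,23.3,9.2,-16.6,8.9
1,K243A,R188A R238A,293,6.6,0.4,5.0,5.1,1.6,4.9
1,K243A,R188A R238A,298,6.8,0.2,-13.3,3.9,20.1,4.0
1,K243A,R188A R238A,303,7.3,0.2,-31.6,8.7,38.9,8.9
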