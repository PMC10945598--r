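variant,temperature_K,event,dG_kJmol,dG_sd,dH_kJmol,dH_sd,mTdS_kJmol,mTdS_sd,dCp_kJmolK,dCp_sd
WT,288,1,-34.0,0.2,-36.0,11.6,2.0,11.5,8.0,1.5
WT,288,2,-30.8,0.1,-43.2,7.3,12.4,7.3,10.1,0.9
WT,288,3,-28.6,0.2,-36.6,8.1,8.0,8.0,9.4,0.9
WT,293,1,-34.4,0.1,4.3,5.4,-38.6,5.4,7.4,1.5
WT,293,2,-31.1,0.2,7.9,2.7,-39.0,2.7,9.1,0.8
WT,293,3,-29.0,0.2,10.9,3.3,-39.8,3.3,8.5,0.6
WT,298,1,-35.2,0.2,45.0,5.8,-80.2,5.9,8.9,1.4
WT,298,2,-32.0,0.2,59.9,2.3,-91.8,2.2,11.7,1.2
WT,298,3,-29.8,0.2,59.1,1.8,-88.9,1.7,10.7,1.5
WT,303,1,-37.0,0.3,86.1,12.1,-123.0,12.4,8.3,1.5
WT,303,2,-34.1,0.2,112.3,7.1,-146.4,7.1,10.6,1.0
WT,303,3,-31.8,0.2,107.7,7.1,-139.5,7.1,9.8,1.1
R78A,288,1,-31.6,0.2,9.6,4.5,-41.2,4.7,-2.6,1.1
R78A,288,2,-28.8,0.3,-13.0,19.1,-15.8,18.8,5.0,1.7
R78A,293,1,-32.2,0.3,-3.5,5.1,-28.6,5.1,-2.6,1.1
R78A,293,2,-29.2,0.1,12.0,11.1,-41.3,11.1,5.0,1.7
R78A,298,1,-32.5,0.2,-16.7,9.6,-15.9,9.6,-2.6,1.1
R78A,298,2,-30.2,0.2,37.1,5.9,-67.2,6.1,5.0,1.7
R188A,288,1,-31.2,0.2,-23.0,8.2,-8.3,8.1,6.4,1.1
R188A,288,2,-27.4,0.4,-39.1,0.5,11.8,0.7,11.2,1.0
R188A,293,1,-31.7,0.1,9.4,3.6,-41.1,3.5,6.1,1.2
R188A,293,2,-27.7,0.5,17.4,4.6,-45.1,4.2,10.7,1.7
R188A,298,1,-32.6,0.1,42.1,3.7,-74.6,3.7,6.9,0.9
R188A,298,2,-28.8,0.2,74.4,8.8,-103.2,8.6,12.1,0.7
R188A,303,1,-34.1,0.1,74.9,8.3,-109.0,8.3,6.6,1.0
R188A,303,2,-31.1,0.1,131.6,12.8,-162.7,12.8,11.5,0.7
R238A,288,1,-30.9,0.1,-66.8,3.4,35.9,3.3,4.8,0.3
R238A,288,2,-29.4,0.2,-57.9,17.9,28.6,17.8,2.8,2.4
R238A,293,1,-30.6,0.1,-42.6,4.0,12.1,3.9,4.1,0.3
R238A,293,2,-29.2,0.2,-43.2,6.5,13.9,6.5,0.9,2.5
R238A,298,1,-30.4,0.1,-17.9,4.8,-12.6,4.8,5.8,0.3
R238A,298,2,-28.6,0.2,-26.8,7.2,-1.9,7.0,5.5,2.4
R238A,303,1,-30.9,0.1,7.2,5.8,-38.1,5.9,5.1,0.3
R238A,303,2,-29.0,0.1,-9.5,18.6,-19.5,18.7,3.7,2.4
K243A,288,1,-32.6,0.1,-48.5,7.3,15.9,7.2,9.9,0.9
K243A,288,2,-28.4,0.3,-31.6,7.3,3.3,7.0,8.5,0.9
K243A,293,1,-32.8,0.2,1.5,3.5,-34.4,3.5,9.1,0.8
K243A,293,2,-28.8,0.2,11.7,3.1,-40.5,3.0,7.3,1.2
K243A,298,1,-33.6,0.1,52.2,3.9,-85.9,4.0,11.2,1.2
K243A,298,2,-29.6,0.2,56.0,2.0,-85.5,2.1,10.3,0.6
K243A,303,1,-35.6,0.2,103.3,8.0,-138.9,8.2,10.3,1.0
K243A,303,2,-31.5,0.2,100.8,5.6,-132.3,5.8,9.1,0.8
K299A,288,1,-31.1,0.1,-22.2,9.5,-8.9,9.4,6.4,1.1
K299A,288,2,-28.8,0.1,-18.8,9.6,-10.0,9.5,7.3,1.0
K299A,288,3,-26.4,0.9,-35.6,71.5,9.3,70.7,11.4,7.1
K299A,293,1,-31.6,0.1,9.9,3.8,-41.5,3.9,5.6,1.1
K299A,293,2,-29.4,0.1,18.0,4.6,-47.4,4.6,6.0,1.0
K299A,293,3,-27.0,0.5,22.7,37.2,-49.6,37.5,9.2,8.6
K299A,298,1,-32.4,0.1,42.7,2.1,-75.1,1.9,7.4,1.2
K299A,298,2,-30.2,0.1,55.9,1.7,-86.1,1.6,9.0,1.1
K299A,298,3,-27.7,0.3,82.9,7.8,-110.6,7.9,14.7,5.1
K299A,303,1,-34.0,0.1,75.8,7.7,-109.8,7.7,6.7,1.2
K299A,303,2,-32.1,0.1,94.3,6.3,-126.4,6.3,7.8,1.1
K299A,303,3,-30.4,0.2,144.1,30.5,-174.5,30.3,12.5,6.4
R78A K299A,288,1,-30.9,0.2,-36.8,5.6,5.9,5.4,4.4,0.8
R78A K299A,288,2,-28.2,0.1,-49.1,5.7,20.9,5.7,12.0,1.4
R78A K299A,293,1,-30.9,0.1,-15.0,2.8,-16.0,2.8,4.4,0.8
R78A K299A,293,2,-28.3,0.1,10.7,9.6,-39.1,9.7,12.0,1.4
R78A K299A,298,1,-31.4,0.1,6.8,3.8,-38.2,3.9,4.4,0.8
R78A K299A,298,2,-29.5,0.3,70.6,15.6,-100.1,15.9,12.0,1.4
R188A R238A,288,1,-29.0,0.4,-93.3,15.2,64.3,14.8,7.8,1.3
R188A R238A,293,1,-28.5,0.2,-53.3,9.2,24.8,9.1,5.9,1.6
R188A R238A,298,1,-27.9,0.1,-11.6,4.7,-16.3,4.6,10.6,1.0
R188A R238A,303,1,-28.8,0.1,30.9,5.9,-59.7,5.9,8.7,1.2
R188A K243A,288,1,-33.0,0.1,-20.3,6.0,-12.6,6.0,4.9,0.6
R188A K243A,288,2,-28.9,0.1,-21.3,3.4,-7.6,3.3,4.8,0.5
R188A K243A,293,1,-33.5,0.1,4.5,3.2,-38.0,3.2,4.0,0.6
R188A K243A,293,2,-29.3,0.1,2.7,3.4,-32.0,3.4,4.2,0.4
R188A K243A,298,1,-34.1,0.1,30.1,1.9,-64.3,1.9,6.2,0.7
R188A K243A,298,2,-29.9,0.1,27.3,5.0,-57.1,5.0,5.6,0.6
R188A K243A,303,1,-35.5,0.1,56.1,4.1,-91.7,4.1,5.3,0.6
R188A K243A,303,2,-31.1,0.1,52.0,7.3,-83.2,7.4,5.0,0.5
R188A K299A,288,1,-26.8,0.1,-15.4,16.2,-11.4,16.0,8.9,2.2
R188A K299A,288,2,-26.9,0.6,-15.7,36.0,-11.1,35.4,5.2,3.8
R188A K299A,293,1,-27.5,0.1,29.5,5.2,-57.0,5.2,7.8,1.3
R188A K299A,293,2,-27.2,0.4,10.1,18.9,-37.3,18.9,5.8,6.0
R188A K299A,298,1,-28.6,0.2,75.2,7.6,-103.8,7.4,10.4,3.5
R188A K299A,298,2,-28.2,0.2,35.4,6.4,-63.6,6.3,4.4,1.4
R188A K299A,303,1,-30.8,0.2,121.4,19.9,-152.2,20.0,9.4,2.6
R188A K299A,303,2,-29.4,0.1,60.5,14.2,-89.9,14.2,5.0,2.8
R238A K243A,288,1,-30.7,0.2,-42.4,8.3,11.8,8.1,-1.2,0.5
R238A K243A,288,2,-28.1,0.1,13.2,9.6,-41.4,9.6,-3.8,2.4
R238A K243A,293,1,-30.8,0.1,-46.9,6.0,16.1,6.0,-4.7,0.3
R238A K243A,293,2,-28.8,0.2,-5.4,4.5,-23.4,4.5,-4.7,1.6
R238A K243A,298,1,-29.6,0.1,-48.4,4.0,18.8,4.1,3.8,0.8
R238A K243A,298,2,-28.8,0.1,-23.3,17.2,-5.5,17.2,-2.5,3.8
R238A K243A,303,1,-29.7,0.1,-48.3,3.4,18.6,3.4,0.4,0.6
R238A K243A,303,2,-28.9,0.6,-40.7,31,11.9,31.5,-3.4,2.9
R188A R238A K243A,288,1,-25.9,0.3,-25.2,5.7,-0.7,5.4,6.2,0.3
R188A R238A K243A,293,1,-26.3,0.3,6.5,3.7,-32.7,3.4,5.3,1.4
R188A R238A K243A,298,1,-26.9,0.2,38.9,0.6,-65.7,0.7,7.6,2.5
R188A R238A K243A,303,1,-28.3,0.2,71.7,3.3,-100.0,3.3,6.7,0.9
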