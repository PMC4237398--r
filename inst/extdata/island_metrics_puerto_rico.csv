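scenario,class,year,AREA_MN,LPI,ED,EDGE_AREA
true,urban,1991,1.184,1.39,25.9,415.6
true,urban,2000,1.182,1.44,28.1,417.7
true,wetland,1991,3.54,0.08,1.76,246.3
true,wetland,2000,7.63,0.09,1.31,185.5
true,forest,1991,8.03,10.3,37,169.2
true,forest,2000,7.56,14.1,39,174.8
outside_urban,forest,1991,7.20,10.4,29,182.6
outside_urban,forest,2000,7.12,14.2,31,181.3
deforestation_only,forest,NA,6.07,7.8,35,196.4
reforestation_only,forest,NA,10.73,19.2,36,136.3
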