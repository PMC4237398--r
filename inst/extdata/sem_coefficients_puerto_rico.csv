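index,class,year,term,estimate
EDGE_AREA,urban,2000,D,56.9
EDGE_AREA,urban,2000,D_sq,-2.73
EDGE_AREA,urban,2000,s,19.98
EDGE_AREA,urban,2000,sigma_s,-38.47
EDGE_AREA,urban,2000,d_p,-0.119
EDGE_AREA,urban,2000,intercept,455.2
EDGE_AREA,urban,1991,D,59.6
EDGE_AREA,urban,1991,D_sq,-3.42
EDGE_AREA,urban,1991,s,20.85
EDGE_AREA,urban,1991,sigma_s,-35.91
EDGE_AREA,urban,1991,d_p,-0.121
EDGE_AREA,urban,1991,intercept,446.0
EDGE_AREA,urban,1977,D,49.6
EDGE_AREA,urban,1977,D_sq,-3.41
EDGE_AREA,urban,1977,s,6.29
EDGE_AREA,urban,1977,sigma_s,-9.31
EDGE_AREA,urban,1977,d_p,-0.063
EDGE_AREA,urban,1977,intercept,233.5
ED,urban,2000,D,-7.96
ED,urban,2000,D_sq,0.519
ED,urban,2000,s,3.58
ED,urban,2000,s_sq,-0.188
ED,urban,2000,sigma_s,9.18
ED,urban,2000,sigma_s_sq,-1.02
ED,urban,2000,d_p,0.00321
ED,urban,2000,intercept,54.9
ED,urban,1991,D,-5.87
ED,urban,1991,D_sq,0.389
ED,urban,1991,s,3.54
ED,urban,1991,s_sq,-0.172
ED,urban,1991,sigma_s,5.30
ED,urban,1991,sigma_s_sq,-0.68
ED,urban,1991,d_p,0.00463
ED,urban,1991,intercept,51.7
ED,urban,1977,D,-3.56
ED,urban,1977,D_sq,0.21
ED,urban,1977,s,1.38
ED,urban,1977,s_sq,-0.066
ED,urban,1977,d_p,0.00631
ED,urban,1977,intercept,22.8
ED,forest,2000,D,3.20
ED,forest,2000,D_sq,-0.23
ED,forest,2000,s,9.34
ED,forest,2000,s_sq,-0.285
ED,forest,2000,sigma_s,-4.42
ED,forest,2000,intercept,40.96
ED,forest,1991,D,3.97
ED,forest,1991,D_sq,-0.33
ED,forest,1991,s,10.20
ED,forest,1991,s_sq,-0.308
ED,forest,1991,sigma_s,-4.71
ED,forest,1991,intercept,33.23
ED,forest,1977,D,0.42
ED,forest,1977,s,4.25
ED,forest,1977,s_sq,-0.136
ED,forest,1977,sigma_s,-1.87
ED,forest,1977,intercept,22.93
AREA_MN,forest,2000,D_sq,0.55
AREA_MN,forest,2000,s,-6.68
AREA_MN,forest,2000,s_sq,0.47
AREA_MN,forest,2000,sigma_s,14.45
AREA_MN,forest,2000,sigma_s_sq,-1.88
AREA_MN,forest,1991,D_sq,1.33
AREA_MN,forest,1991,s,-4.41
AREA_MN,forest,1991,s_sq,0.38
AREA_MN,forest,1991,sigma_s,12.63
AREA_MN,forest,1991,sigma_s_sq,-1.65
AREA_MN,forest,1977,D_sq,1.10
AREA_MN,forest,1977,s,2.59
AREA_MN,forest,1977,s_sq,0.62
AREA_MN,forest,1977,sigma_s,6.93
AREA_MN,forest,1977,sigma_s_sq,-2.93
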