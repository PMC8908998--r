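sample_id,subject_id,site,diagnosis,tbsrtc,tissue,n_cells,fpol_mean,fpol_sd
1-T,1,UMMC,MTC,VI,tumor,247,0.270,0.028
1-N,1,UMMC,Normal,none,normal,47,0.209,0.014
2-T,2,UMMC,PTC,VI,tumor,137,0.253,0.016
2-N,2,UMMC,Normal,none,normal,84,0.211,0.015
3-T,3,UMMC,PTC,VI,tumor,79,0.263,0.019
3-N,3,UMMC,Normal,none,normal,72,0.219,0.012
4-T,4,UMMC,PTC,VI,tumor,103,0.257,0.014
4-N,4,UMMC,Normal,none,normal,52,0.220,0.012
5-T,5,LGH,PTC,V,tumor,57,0.263,0.015
5-N,5,LGH,Normal,none,normal,125,0.215,0.018
6-T,6,LGH,PTC,V,tumor,204,0.276,0.019
7-T,7,LGH,PTC,IV,tumor,84,0.260,0.014
8-T,8,LGH,PTC,III,tumor,128,0.268,0.019
9-T,9,LGH,PTC,III,tumor,210,0.259,0.018
10-T,10,LGH,PTC,III,tumor,254,0.263,0.016
11-T,11,UMMC,FTC,IV,tumor,89,0.262,0.019
11-N,11,UMMC,Normal,none,normal,25,0.221,0.024
12-T,12,UMMC,FTC,III,tumor,94,0.250,0.015
12-N,12,UMMC,Normal,none,normal,59,0.210,0.012
13-T,13,LGH,FTC,III,tumor,191,0.246,0.016
14-T,14,UMMC,FTA,III,tumor,134,0.215,0.018
14-N,14,UMMC,Normal,none,normal,102,0.205,0.021
15-T,15,UMMC,FTA,III,tumor,145,0.211,0.021
15-N,15,UMMC,Normal,none,normal,90,0.216,0.010
16-T,16,LGH,FTA,III,tumor,129,0.204,0.025
16-N,16,LGH,Normal,none,normal,86,0.219,0.021
17-T,17,UMMC,MNG,II,tumor,70,0.207,0.026
18-1,18,UMMC,MNG,II,tumor,50,0.196,0.025
18-2,18,UMMC,MNG,II,tumor,51,0.210,0.019
19-T,19,LGH,MNG,II,tumor,145,0.196,0.015
20-N,20,LGH,Normal,none,normal,100,0.221,0.014
21-N,21,LGH,Normal,none,normal,78,0.204,0.043
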