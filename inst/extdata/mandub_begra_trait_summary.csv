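trait,trait_name,isolate,condition,min,max,mean,aaa_p,significance,n_genes
1,necrosis_pct,IPO86036,polytunnel,6.67,96.82,51.26,0.48,,4
2,pycnidia_pct,IPO86036,polytunnel,0.26,58.57,27.36,2.06,*,3
3,necrosis_pct,IPO86036,growth_chamber,2.65,98.26,45.48,4.97,**,2
4,pycnidia_pct,IPO86036,growth_chamber,0.11,63.47,18.54,13.25,***,3
5,necrosis_pct,IPO92006,polytunnel,1.71,94.58,51.57,-3.42,*,3
6,pycnidia_pct,IPO92006,polytunnel,0,47.31,13.28,10.37,***,3
7,necrosis_pct,IPO92006,growth_chamber,7.33,72.55,35.76,4.18,**,3
8,pycnidia_pct,IPO92006,growth_chamber,0.39,36.46,13.20,5.23,***,4
9,necrosis_pct,IPO88004,polytunnel,7.12,99.8,80.30,-26.84,***,3
10,pycnidia_pct,IPO88004,polytunnel,0.01,59.65,13.87,15.96,***,3
11,necrosis_pct,IPO88004,growth_chamber,5.73,99.09,59.98,-7.57,**,2
12,pycnidia_pct,IPO88004,growth_chamber,1.13,88.57,39.78,5.07,**,2
13,heading_date,IPO86036,polytunnel,52.5,95,73.27,0.48,,5
14,heading_date,IPO92006,polytunnel,52.5,100,79.15,-2.90,,5
15,heading_date,IPO88004,polytunnel,50,105,82.84,-5.34,*,4
16,height_cm,IPO86036,polytunnel,150,159,153.07,1.43,,5
17,height_cm,IPO92006,polytunnel,150,159,153.01,1.49,,4
18,height_cm,IPO88004,polytunnel,146,160.5,152.35,0.90,,5
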