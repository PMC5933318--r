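id,tag_type,start,end,duration_days,distance_km,ars_speed,transit_speed
1,Spot,2013-04-01,2013-05-15,45,1028.6,0.97 ± 1.2 (0.05–5.7),na
2a,Spot,2015-04-09,2015-04-25,17,509.7,1.14 ± 1.3 (0.1–3.8),na
2b,Spot,2015-05-31,2015-07-06,37,313.2,0.36 ± 0.3 (0.02–0.9),na
3,Spot,2015-04-14,2015-07-05,83,7086.1,na,4.17 ± 1.1 (2.0–6.1)
4,MK10,2015-04-09,2015-06-12,65,5102.9,na,3.55 ± 1.2 (0.8–7.1)
5,MK10,2015-04-16,2015-06-09,55,3923.7,na,4.05 ± 1.1 (2.0–6.3)
6,MK10,2015-04-17,2015-09-24,161,7420.3,0.52 ± 0.5 (0.01–2.4),5.43 ± 1.7 (2.6–10.2)
7,MK10,2015-04-13,2015-05-03,21,143.7,0.34 ± 0.4 (0.02–1.1),na
8,Spot,2016-04-10,2016-05-04,25,188.8,0.34 ± 0.3 (0.04–0.8),na
9,Spot,2016-04-04,2016-04-25,23,648.0,na,3.1 ± 1.1 (1.9–4.0)
10,Spot,2016-04-05,2016-10-22,201,8820.1,0.78 ± 0.9 (0.03–3.9),5.2 ± 1.1 (2.3–6.9)
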