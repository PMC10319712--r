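id,name,parent,length_cm,prox_diam_cm,dist_diam_cm,distensibility_per_Pa,terminal
1,ascending_aorta,NA,4.0,3.00,2.90,3.6e-05,0
2,aortic_arch_a,1,3.0,2.90,2.80,3.4e-05,0
3,aortic_arch_b,2,4.0,2.80,2.60,3.3e-05,0
4,thoracic_aorta_a,3,6.0,2.60,2.35,3.1e-05,0
5,thoracic_aorta_b,4,10.0,2.35,2.00,2.9e-05,0
6,abdominal_aorta_a,5,6.0,2.00,1.75,2.7e-05,0
7,abdominal_aorta_b,6,10.0,1.75,1.40,2.5e-05,0
8,brachiocephalic,1,3.5,1.25,1.15,2.2e-05,0
9,right_common_carotid,8,17.0,0.75,0.65,1.9e-05,0
10,right_carotid_bed,9,15.0,0.50,0.45,1.5e-05,1
11,right_subclavian,8,3.5,0.90,0.80,2.0e-05,0
12,right_brachial,11,40.0,0.65,0.50,1.4e-05,0
13,right_forearm,12,25.0,0.40,0.35,1.2e-05,1
14,left_common_carotid,2,19.0,0.75,0.65,1.9e-05,0
15,left_carotid_bed,14,15.0,0.50,0.45,1.5e-05,1
16,left_subclavian,3,3.5,0.90,0.80,2.0e-05,0
17,left_brachial,16,40.0,0.65,0.50,1.4e-05,0
18,left_forearm,17,25.0,0.40,0.35,1.2e-05,1
19,splanchnic,6,6.0,0.90,0.65,1.8e-05,1
20,renal,6,3.0,0.70,0.55,1.8e-05,1
21,right_common_iliac,7,6.0,0.80,0.70,1.6e-05,0
22,left_common_iliac,7,6.0,0.80,0.70,1.6e-05,0
23,right_leg,21,44.0,0.60,0.45,1.1e-05,1
24,left_leg,22,44.0,0.60,0.45,1.1e-05,1
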