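region_id,name,lobe,class,canonical_network
1,Precentral_L,frontal,cortical,motor
2,Precentral_R,frontal,cortical,motor
3,Frontal_Sup_L,frontal,cortical,frontoparietal
4,Frontal_Sup_R,frontal,cortical,frontoparietal
5,Frontal_Sup_Orb_L,frontal,cortical,limbic
6,Frontal_Sup_Orb_R,frontal,cortical,limbic
7,Frontal_Mid_L,frontal,cortical,frontoparietal
8,Frontal_Mid_R,frontal,cortical,frontoparietal
9,Frontal_Mid_Orb_L,frontal,cortical,limbic
10,Frontal_Mid_Orb_R,frontal,cortical,limbic
11,Frontal_Inf_Oper_L,frontal,cortical,frontoparietal
12,Frontal_Inf_Oper_R,frontal,cortical,frontoparietal
13,Frontal_Inf_Tri_L,frontal,cortical,frontoparietal
14,Frontal_Inf_Tri_R,frontal,cortical,frontoparietal
15,Frontal_Inf_Orb_L,frontal,cortical,limbic
16,Frontal_Inf_Orb_R,frontal,cortical,limbic
17,Rolandic_Oper_L,frontal,cortical,motor
18,Rolandic_Oper_R,frontal,cortical,motor
19,Supp_Motor_Area_L,frontal,cortical,motor
20,Supp_Motor_Area_R,frontal,cortical,motor
21,Olfactory_L,frontal,cortical,limbic
22,Olfactory_R,frontal,cortical,limbic
23,Frontal_Sup_Medial_L,frontal,cortical,default
24,Frontal_Sup_Medial_R,frontal,cortical,default
25,Frontal_Med_Orb_L,frontal,cortical,default
26,Frontal_Med_Orb_R,frontal,cortical,default
27,Rectus_L,frontal,cortical,limbic
28,Rectus_R,frontal,cortical,limbic
29,Insula_L,insula,cortical,salience
30,Insula_R,insula,cortical,salience
31,Cingulum_Ant_L,limbic,cortical,default
32,Cingulum_Ant_R,limbic,cortical,default
33,Cingulum_Mid_L,limbic,cortical,limbic
34,Cingulum_Mid_R,limbic,cortical,limbic
35,Cingulum_Post_L,limbic,cortical,default
36,Cingulum_Post_R,limbic,cortical,default
37,Hippocampus_L,limbic,subcortical,limbic
38,Hippocampus_R,limbic,subcortical,limbic
39,ParaHippocampal_L,limbic,cortical,limbic
40,ParaHippocampal_R,limbic,cortical,limbic
41,Amygdala_L,limbic,subcortical,limbic
42,Amygdala_R,limbic,subcortical,limbic
43,Calcarine_L,occipital,cortical,visual
44,Calcarine_R,occipital,cortical,visual
45,Cuneus_L,occipital,cortical,visual
46,Cuneus_R,occipital,cortical,visual
47,Lingual_L,occipital,cortical,visual
48,Lingual_R,occipital,cortical,visual
49,Occipital_Sup_L,occipital,cortical,visual
50,Occipital_Sup_R,occipital,cortical,visual
51,Occipital_Mid_L,occipital,cortical,visual
52,Occipital_Mid_R,occipital,cortical,visual
53,Occipital_Inf_L,occipital,cortical,visual
54,Occipital_Inf_R,occipital,cortical,visual
55,Fusiform_L,temporal,cortical,visual
56,Fusiform_R,temporal,cortical,visual
57,Postcentral_L,parietal,cortical,motor
58,Postcentral_R,parietal,cortical,motor
59,Parietal_Sup_L,parietal,cortical,frontoparietal
60,Parietal_Sup_R,parietal,cortical,frontoparietal
61,Parietal_Inf_L,parietal,cortical,frontoparietal
62,Parietal_Inf_R,parietal,cortical,frontoparietal
63,SupraMarginal_L,parietal,cortical,frontoparietal
64,SupraMarginal_R,parietal,cortical,frontoparietal
65,Angular_L,parietal,cortical,default
66,Angular_R,parietal,cortical,default
67,Precuneus_L,parietal,cortical,default
68,Precuneus_R,parietal,cortical,default
69,Paracentral_Lobule_L,parietal,cortical,motor
70,Paracentral_Lobule_R,parietal,cortical,motor
71,Caudate_L,subcortical,subcortical,subcortical
72,Caudate_R,subcortical,subcortical,subcortical
73,Putamen_L,subcortical,subcortical,subcortical
74,Putamen_R,subcortical,subcortical,subcortical
75,Pallidum_L,subcortical,subcortical,subcortical
76,Pallidum_R,subcortical,subcortical,subcortical
77,Thalamus_L,subcortical,subcortical,subcortical
78,Thalamus_R,subcortical,subcortical,subcortical
79,Heschl_L,temporal,cortical,motor
80,Heschl_R,temporal,cortical,motor
81,Temporal_Sup_L,temporal,cortical,motor
82,Temporal_Sup_R,temporal,cortical,motor
83,Temporal_Pole_Sup_L,temporal,cortical,limbic
84,Temporal_Pole_Sup_R,temporal,cortical,limbic
85,Temporal_Mid_L,temporal,cortical,default
86,Temporal_Mid_R,temporal,cortical,default
87,Temporal_Pole_Mid_L,temporal,cortical,limbic
88,Temporal_Pole_Mid_R,temporal,cortical,limbic
89,Temporal_Inf_L,temporal,cortical,limbic
90,Temporal_Inf_R,temporal,cortical,limbic
91,Cerebelum_Crus1_L,cerebellum,cerebellar,cerebellum
92,Cerebelum_Crus1_R,cerebellum,cerebellar,cerebellum
93,Cerebelum_Crus2_L,cerebellum,cerebellar,cerebellum
94,Cerebelum_Crus2_R,cerebellum,cerebellar,cerebellum
95,Cerebelum_3_L,cerebellum,cerebellar,cerebellum
96,Cerebelum_3_R,cerebellum,cerebellar,cerebellum
97,Cerebelum_4_5_L,cerebellum,cerebellar,cerebellum
98,Cerebelum_4_5_R,cerebellum,cerebellar,cerebellum
99,Cerebelum_6_L,cerebellum,cerebellar,cerebellum
100,Cerebelum_6_R,cerebellum,cerebellar,cerebellum
101,Cerebelum_7b_L,cerebellum,cerebellar,cerebellum
102,Cerebelum_7b_R,cerebellum,cerebellar,cerebellum
103,Cerebelum_8_L,cerebellum,cerebellar,cerebellum
104,Cerebelum_8_R,cerebellum,cerebellar,cerebellum
105,Cerebelum_9_L,cerebellum,cerebellar,cerebellum
106,Cerebelum_9_R,cerebellum,cerebellar,cerebellum
107,Cerebelum_10_L,cerebellum,cerebellar,cerebellum
108,Cerebelum_10_R,cerebellum,cerebellar,cerebellum
109,Vermis_1_2,cerebellum,cerebellar,cerebellum
110,Vermis_3,cerebellum,cerebellar,cerebellum
111,Vermis_4_5,cerebellum,cerebellar,cerebellum
112,Vermis_6,cerebellum,cerebellar,cerebellum
113,Vermis_7,cerebellum,cerebellar,cerebellum
114,Vermis_8,cerebellum,cerebellar,cerebellum
115,Vermis_9,cerebellum,cerebellar,cerebellum
116,Vermis_10,cerebellum,cerebellar,cerebellum
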