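index,code,category,tbs_targets,detection_class
1,AGC_A,glandular-intraepithelial,AGC_NOS|AGC_FN|AIS|ADC,AGC
2,AGC_B,glandular-intraepithelial,AGC_NOS|AGC_FN|AIS|ADC,AGC
3,ASC_L_S,squamous-intraepithelial,ASCUS|LSIL|ASCH|HSIL|SCC,ASC_L_S
4,KC,squamous-intraepithelial,LSIL,KC
5,ASC_L_F,squamous-intraepithelial,ASCUS|LSIL|ASCH|HSIL|SCC,KC
6,ASC_H_B,squamous-intraepithelial,ASCUS|ASCH|HSIL|SCC,ASC_H
7,ASC_H_M,squamous-intraepithelial,ASCUS|ASCH|HSIL|SCC,ASC_H
8,ASC_H_S,squamous-intraepithelial,ASCUS|ASCH|HSIL|SCC,ASC_H
9,SCC_R,squamous-intraepithelial,SCC,ASC_H
10,SCC_G,squamous-intraepithelial,SCC,ASC_H
11,MC,normal,NILM,excluded
12,SC,normal,NILM,SC
13,RC,normal,NILM,excluded
14,GEC,normal,NILM,excluded
15,EMC,EMC,EMC,EMC
16,TRI,infectious,TRI,TRI
17,CAN,infectious,CAN,CAN
18,HSV,infectious,HSV,HSV
19,ACTINO,infectious,ACTINO,ACTINO
20,CC,infectious,CC,CC
21,PH,evidence-of-infection,NILM,PH
22,Neutrophils,normal,NILM,excluded
23,Mucus,normal,NILM,excluded
24,Debris,normal,NILM,excluded
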