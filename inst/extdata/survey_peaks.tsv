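site_id	region_id	center
SSV	FP	694
SSV	R1	1024
SSV	R1	1043
SSV	R1	1075
SSV	R1	1080
SSV	R1	1147
SSV	R2	1328
SSV	R2	1360
SSV	R2	1391
SSV	R2	1421
SSV	R2	1451
SSV	R2	1490
SSV	R3	1640
SSV	R3	1654
SSV	R3	1664
SSV	R3	1713
SSV	R3	1743
SSV	R4	3058
SSV	R4	3075
SSV	R4	3231
SSV	R4	3296
SSV	R4	3336
SSV	R4	3412
SSV	R4	3463
SSV	R4	3518
SMTL	FP	625
SMTL	FP	698
SMTL	FP	836
SMTL	FP	868
SMTL	R1	1011
SMTL	R1	1050
SMTL	R1	1086
SMTL	R1	1104
SMTL	R1	1124
SMTL	R1	1134
SMTL	R1	1155
SMTL	R2	1273
SMTL	R2	1313
SMTL	R2	1350
SMTL	R2	1375
SMTL	R2	1398
SMTL	R2	1418
SMTL	R2	1441
SMTL	R2	1466
SMTL	R2	1511
SMTL	R3	1629
SMTL	R3	1656
SMTL	R3	1682
SMTL	R3	1688
SMTL	R3	1713
SMTL	R3	1768
SMTL	R4	2863
SMTL	R4	2916
SMTL	R4	2986
SMTL	R4	2966
SMTL	R4	3061
SMTL	R4	3119
SMTL	R4	3189
SMTL	R4	3254
SMTL	R4	3308
SMTL	R4	3411
TL	FP	618
TL	FP	682.5
TL	FP	836
TL	FP	868
TL	FP	993
TL	R1	994
TL	R1	1065
TL	R1	1074
TL	R1	1097
TL	R1	1115
TL	R1	1131
TL	R1	1155
TL	R1	1165
TL	R2	1307
TL	R2	1328
TL	R2	1370
TL	R2	1408
TL	R2	1452
TL	R2	1516
TL	R3	1642
TL	R3	1653
TL	R3	1688
TL	R3	1713
TL	R4	2848
TL	R4	2916
TL	R4	2965
TL	R4	3020
TL	R4	3077
TL	R4	3129
TL	R4	3165
TL	R4	3216
TL	R4	3266
TL	R4	3332
TL	R4	3405
TL	R4	3496
C	FP	612
C	FP	623
C	FP	692
C	FP	698
C	FP	836
C	R1	1081
C	R1	1089
C	R1	1103
C	R1	1124
C	R1	1149
C	R2	1267
C	R2	1291
C	R2	1312
C	R2	1335
C	R2	1362
C	R2	1395
C	R2	1396
C	R3	1634
C	R3	1661
C	R3	1685
C	R3	1713
C	R3	1768
C	R3	1793
C	R4	2814
C	R4	2902
C	R4	2949
C	R4	3007
C	R4	3050
C	R4	3094
C	R4	3152
C	R4	3203
C	R4	3257
C	R4	3340
C	R4	3424
C	R4	3522
SPC	FP	612
SPC	FP	623
SPC	FP	698
SPC	FP	836
SPC	FP	868
SPC	R1	987
SPC	R1	1033
SPC	R1	1076
SPC	R1	1086
SPC	R1	1119
SPC	R1	1151
SPC	R1	1157
SPC	R2	1276
SPC	R2	1318
SPC	R2	1363
SPC	R2	1400
SPC	R2	1433
SPC	R2	1458
SPC	R2	1514
SPC	R3	1610
SPC	R3	1638
SPC	R3	1667
SPC	R3	1694
SPC	R3	1713
SPC	R3	1743
SPC	R3	1768
SPC	R4	2896
SPC	R4	3048
SPC	R4	3116
SPC	R4	3191
SPC	R4	3342
SPC	R4	3495
SPC	R4	3502
SAC	FP	612
SAC	FP	692
SAC	FP	836
SAC	FP	868
SAC	R1	1023
SAC	R1	1074
SAC	R1	1093
SAC	R1	1120
SAC	R1	1152
SAC	R1	1168
SAC	R2	1285
SAC	R2	1333
SAC	R2	1367
SAC	R2	1390
SAC	R2	1413
SAC	R2	1439
SAC	R2	1475
SAC	R2	1522
SAC	R3	1640
SAC	R3	1651
SAC	R3	1660
SAC	R3	1676
SAC	R3	1699
SAC	R3	1713
SAC	R4	2836
SAC	R4	2902
SAC	R4	2939
SAC	R4	3008
SAC	R4	3077
SAC	R4	3108
SAC	R4	3173
SAC	R4	3225
SAC	R4	3288
SAC	R4	3356
SAC	R4	3389
SAC	R4	3455
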