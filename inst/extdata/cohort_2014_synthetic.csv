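id,phase_index,cadence,n_loading,n_maintenance,weight_kg
P001,1,weekly,1,10,77.513765
P001,2,q3w,0,3,77.513765
P002,1,weekly,1,10,66.597872
P002,2,q3w,0,3,66.597872
P003,1,weekly,1,10,48.771876
P003,2,q3w,0,3,48.771876
P004,1,weekly,1,10,65.006059
P004,2,q3w,0,3,65.006059
P005,1,weekly,1,10,60.89723
P005,2,q3w,0,3,60.89723
P006,1,weekly,1,10,54.646132
P006,2,q3w,0,3,54.646132
P007,1,weekly,1,10,55.067857
P007,2,q3w,0,3,55.067857
P008,1,weekly,1,10,57.800648
P008,2,q3w,0,3,57.800648
P009,1,weekly,1,10,87.041213
P009,2,q3w,0,3,87.041213
P010,1,weekly,1,10,61.222107
P010,2,q3w,0,3,61.222107
P011,1,weekly,1,10,59.564933
P011,2,q3w,0,3,59.564933
P012,1,weekly,1,10,65.637597
P012,2,q3w,0,3,65.637597
P013,1,weekly,1,10,57.431163
P013,2,q3w,0,3,57.431163
P014,1,weekly,1,10,85.780941
P014,2,q3w,0,3,85.780941
P015,1,weekly,1,10,78.002221
P015,2,q3w,0,3,78.002221
P016,1,weekly,1,10,76.098225
P016,2,q3w,0,3,76.098225
P017,1,weekly,1,10,79.004846
P017,2,q3w,0,3,79.004846
P018,1,weekly,1,10,68.937243
P018,2,q3w,0,3,68.937243
P019,1,weekly,1,10,45.126282
P019,2,q3w,0,3,45.126282
P020,1,weekly,1,10,69.640327
P020,2,q3w,0,3,69.640327
P021,1,weekly,1,10,55.481003
P021,2,q3w,0,3,55.481003
P022,1,weekly,1,8,59.903587
P022,2,q3w,0,3,59.903587
P023,1,weekly,1,8,43.781658
P023,2,q3w,0,3,43.781658
P024,1,weekly,1,8,66.922543
P024,2,q3w,0,3,66.922543
P025,1,weekly,1,8,67.249955
P025,2,q3w,0,3,67.249955
P026,1,weekly,1,8,73.895992
P026,2,q3w,0,3,73.895992
P027,1,weekly,1,8,53.325631
P027,2,q3w,0,3,53.325631
P028,1,weekly,1,8,62.182277
P028,2,q3w,0,3,62.182277
P029,1,weekly,1,8,49.327871
P029,2,q3w,0,3,49.327871
P030,1,weekly,1,8,69.998887
P030,2,q3w,0,3,69.998887
P031,1,weekly,1,8,68.251254
P031,2,q3w,0,3,68.251254
P032,1,weekly,1,8,93.170524
P032,2,q3w,0,3,93.170524
P033,1,weekly,1,8,66.275675
P033,2,q3w,0,3,66.275675
P034,1,weekly,1,8,63.4406
P034,2,q3w,0,3,63.4406
P035,1,weekly,1,8,60.569403
P035,2,q3w,0,3,60.569403
P036,1,weekly,1,8,67.914051
P036,2,q3w,0,3,67.914051
P037,1,weekly,1,8,89.002001
P037,2,q3w,0,3,89.002001
P038,1,weekly,1,8,70.362441
P038,2,q3w,0,3,70.362441
P039,1,weekly,1,8,64.692024
P039,2,q3w,0,3,64.692024
P040,1,weekly,1,8,74.321508
P040,2,q3w,0,4,74.321508
P041,1,weekly,1,8,52.395252
P041,2,q3w,0,4,52.395252
P042,1,weekly,1,8,72.263093
P042,2,q3w,0,4,72.263093
P043,1,weekly,1,8,87.685463
P043,2,q3w,0,4,87.685463
P044,1,weekly,1,8,89.674174
P044,2,q3w,0,4,89.674174
P045,1,weekly,1,8,74.754315
P045,2,q3w,0,4,74.754315
P046,1,weekly,1,11,81.116133
P046,2,q3w,0,3,81.116133
P047,1,weekly,1,11,47.018237
P047,2,q3w,0,3,47.018237
P048,1,weekly,1,11,49.870348
P048,2,q3w,0,3,49.870348
P049,1,weekly,1,11,45.773102
P049,2,q3w,0,3,45.773102
P050,1,weekly,1,11,52.865713
P050,2,q3w,0,3,52.865713
P051,1,weekly,1,11,54.215446
P051,2,q3w,0,3,54.215446
P052,1,weekly,1,11,46.403591
P052,2,q3w,0,3,46.403591
P053,1,weekly,1,11,79.519255
P053,2,q3w,0,3,79.519255
P054,1,q3w,1,10,57.711419
P055,1,q3w,1,10,56.345164
P056,1,q3w,1,10,80.288396
P057,1,q3w,1,10,55.243801
P058,1,q3w,1,10,71.383412
P059,1,q3w,1,10,65.161198
P060,1,q3w,1,10,70.864387
P061,1,q3w,1,10,77.395601
P062,1,q3w,1,10,42.230656
P063,1,q3w,1,10,54.117917
P064,1,q3w,1,10,58.261305
P065,1,q3w,1,10,69.865249
P066,1,q3w,1,10,79.535596
P067,1,q3w,1,10,48.008941
P068,1,q3w,1,10,60.241176
P069,1,q3w,1,10,62.707427
P070,1,q3w,1,10,58.816346
P071,1,q3w,1,10,56.618498
P072,1,q3w,1,10,66.733264
P073,1,q3w,1,10,75.421625
P074,1,q3w,1,10,57.437731
P075,1,q3w,1,10,69.384283
P076,1,q3w,1,10,42.686815
P077,1,q3w,1,10,61.7482
P078,1,q3w,1,10,52.044488
P079,1,q3w,1,10,57.164523
P080,1,q3w,1,10,93.290109
P081,1,q3w,1,10,45.689519
P082,1,q3w,1,10,52.653545
P083,1,q3w,1,10,67.574855
P084,1,q3w,1,10,82.673348
P085,1,q3w,1,10,46.091859
P086,1,q3w,0,8,63.375
P087,1,q3w,0,8,65.929689
P088,1,q3w,0,8,81.061889
P089,1,q3w,0,8,48.374194
P090,1,q3w,0,8,52.350888
P091,1,q3w,0,8,85.26104
P092,1,q3w,0,8,54.402514
P093,1,q3w,0,8,47.637791
P094,1,q3w,0,8,53.541103
P095,1,q3w,0,8,90.072606
P096,1,q3w,0,8,94.422276
P097,1,q3w,0,8,51.734148
P098,1,q3w,0,8,74.798056
P099,1,q3w,0,8,91.116062
P100,1,q3w,0,8,67.149121
P101,1,q3w,0,8,43.578562
P102,1,q3w,0,8,88.069019
P103,1,q3w,0,8,50.116783
P104,1,q3w,0,8,58.538044
P105,1,q3w,0,8,59.663438
P106,1,q3w,0,8,48.733679
P107,1,q3w,0,8,89.057173
P108,1,q3w,0,8,76.719879
P109,1,q3w,0,8,73.023582
P110,1,q3w,0,8,78.089763
P111,1,q3w,0,8,64.789218
P112,1,q3w,0,8,53.830854
P113,1,q3w,0,8,78.802908
P114,1,q3w,0,8,65.541238
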