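"position_um","value_ppm"
0,500
2,500
4,500
6,500
8,500
10,860
12,860
14,860
16,860
18,860
20,860
22,860
24,860
26,860
28,860
30,860
32,860
34,860
36,860
38,860
40,860
42,860
44,860
46,860
48,860
50,860
52,860
54,860
56,860
58,860
60,860
62,860
64,860
66,860
68,860
70,860
72,860
74,860
76,860
78,500
80,500
82,500
84,500
86,320
88,320
90,320
92,320
94,320
96,320
98,320
100,320
102,320
104,320
106,320
108,320
110,320
112,320
114,320
116,320
118,320
120,320
122,320
124,320
126,320
128,320
130,320
132,320
134,320
136,320
138,320
140,320
142,320
144,320
146,320
148,320
150,320
152,320
154,500
156,500
158,500
160,500
162,500
164,500
166,860
168,860
170,860
172,860
174,860
176,860
178,860
180,860
182,860
184,860
186,860
188,860
190,860
192,860
194,860
196,860
198,860
200,860
202,860
204,860
206,860
208,860
210,860
212,860
214,860
216,860
218,860
220,860
222,860
224,860
226,860
228,860
230,860
232,860
234,860
236,860
238,860
240,860
242,860
244,860
246,860
248,860
250,860
252,860
254,860
256,860
258,860
260,860
262,860
264,860
266,860
268,860
270,860
272,860
274,860
276,860
278,860
280,860
282,860
284,860
286,860
288,860
290,860
292,860
294,860
296,860
298,860
300,860
302,860
304,860
306,500
308,500
310,500
312,500
314,500
316,500
318,500
320,500
322,500
324,500
326,320
328,320
330,320
332,320
334,320
336,320
338,320
340,320
342,320
344,320
346,320
348,320
350,320
352,320
354,320
356,320
358,320
360,320
362,320
364,320
366,320
368,320
370,320
372,320
374,320
376,320
378,320
380,320
382,320
384,320
386,320
388,320
390,320
392,320
394,320
396,320
398,320
400,320
402,320
404,320
406,320
408,320
410,320
412,320
414,320
416,320
418,320
420,320
422,320
424,320
426,320
428,320
430,320
432,500
434,500
436,500
438,500
440,500
442,500
444,500
446,500
448,500
450,860
452,860
454,860
456,860
458,860
460,860
462,860
464,860
466,860
468,860
470,860
472,860
474,860
476,860
478,860
480,860
482,860
484,860
486,860
488,860
490,860
492,860
494,860
496,860
498,860
500,860
502,860
504,860
506,860
508,860
510,860
512,860
514,860
516,860
518,860
520,860
522,860
524,860
526,860
528,860
530,860
532,860
534,860
536,860
538,860
540,860
542,860
544,860
546,860
548,500
550,500
552,500
554,500
556,500
558,500
560,500
562,500
564,500
566,500
568,500
570,500
572,320
574,320
576,320
578,320
580,320
582,320
584,320
586,320
588,320
590,320
592,320
594,320
596,320
598,320
600,320
602,320
604,320
606,320
608,320
610,320
612,320
614,320
616,320
618,320
620,320
622,320
624,320
626,320
628,320
630,320
632,320
634,320
636,320
638,320
640,320
642,320
644,320
646,320
648,320
650,320
652,320
654,320
656,320
658,320
660,320
662,320
664,320
666,320
668,320
670,320
672,320
674,320
676,320
678,320
680,320
682,320
684,320
686,320
688,320
690,320
692,320
694,320
696,320
698,320
700,320
702,320
704,320
706,320
708,320
710,320
712,320
714,320
716,320
718,320
720,320
722,320
724,320
726,320
728,320
730,320
732,320
734,320
736,320
738,320
740,320
742,320
744,320
746,320
748,320
750,500
752,500
754,500
756,500
758,500
760,500
762,500
764,500
766,500
768,500
770,500
772,500
774,500
776,500
778,500
780,500
782,500
784,500
786,500
788,500
790,500
792,500
794,500
796,500
798,500
800,500
802,500
804,500
806,500
808,500
810,500
812,500
814,500
816,500
818,500
820,500
822,500
824,500
826,500
828,500
830,500
832,500
834,500
836,500
838,500
840,500
842,500
844,500
846,500
848,500
850,500
852,500
854,500
856,500
858,500
860,500
862,500
864,500
866,500
868,500
870,500
872,500
874,500
876,500
878,500
880,500
882,500
884,500
886,500
888,500
890,500
892,500
894,500
896,500
898,500
900,500
902,500
904,500
906,500
908,500
910,500
912,500
914,500
916,500
918,500
920,500
922,500
924,500
926,500
928,500
930,500
932,500
934,500
936,500
938,500
940,500
942,500
944,500
946,500
948,500
950,500
952,500
954,500
956,500
958,500
960,500
962,500
964,500
966,500
968,500
970,500
972,500
974,500
976,500
978,500
980,500
982,500
984,500
986,500
988,500
990,500
992,500
994,500
996,860
998,860
1000,860
1002,860
1004,860
1006,860
1008,860
1010,860
1012,860
1014,860
1016,860
1018,860
1020,860
1022,860
1024,860
1026,860
1028,860
1030,860
1032,860
1034,860
1036,860
1038,860
1040,860
1042,860
1044,860
1046,860
1048,860
1050,860
1052,860
1054,860
1056,860
1058,860
1060,860
1062,860
1064,860
1066,860
1068,860
1070,860
1072,860
1074,860
1076,860
1078,860
1080,860
1082,860
1084,860
1086,860
1088,860
1090,860
1092,860
1094,860
1096,860
1098,860
1100,860
1102,860
1104,860
1106,860
1108,860
1110,860
1112,860
1114,860
1116,860
1118,860
1120,860
1122,860
1124,860
1126,860
1128,860
1130,860
1132,860
1134,860
1136,860
1138,860
1140,860
1142,860
1144,500
1146,500
1148,500
1150,500
1152,500
1154,500
1156,500
1158,500
1160,500
1162,500
1164,500
1166,320
1168,320
1170,320
1172,320
1174,320
1176,320
1178,320
1180,320
1182,320
1184,320
1186,320
1188,320
1190,320
1192,320
1194,320
1196,320
1198,320
1200,320
1202,320
1204,320
1206,320
1208,320
1210,320
1212,320
1214,320
1216,320
1218,320
1220,320
1222,320
1224,320
1226,320
1228,320
1230,320
1232,320
1234,320
1236,320
1238,320
1240,320
1242,320
1244,320
1246,320
1248,320
1250,320
1252,320
1254,320
1256,320
1258,320
1260,320
1262,320
1264,320
1266,320
1268,320
1270,320
1272,320
1274,320
1276,320
1278,320
1280,320
1282,320
1284,320
1286,320
1288,320
1290,320
1292,320
1294,320
1296,320
1298,320
1300,320
1302,320
1304,320
1306,320
1308,320
1310,320
1312,500
1314,500
1316,500
1318,500
1320,500
1322,500
1324,500
1326,500
1328,500
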