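gene	chromosome	transcript	aa	mw_kda	signals
TaHsfA1-1	4A	AA0958570	521	57.36	(126)RRKP(252)KKRR(464)DSFWEQFLCA
TaHsfA1-2	5B	AA1285550	529	58.19	(129)RRKP(256)KKRR(472)DSFWEQFLCA
TaHsfA1-3	5D	AA1410370	522	57.46	(124)RRKP(249)KKRR(465)DSFWEQFLCA
TaHsfA2-1	5A	AA1215960	346	38.99	(157)LKRDRQLLM(125)KRRKP(223)RKELEDAISNKRRRRID(313)DDFWEDLLHE(2)SHRM(342)AEKL
TaHsfA2-2	5B	AA2081150	353	39.73	(164)LKRDRQLLM(132)KRRKP(230)RKELEDAISNKRRRRID(320)DDFWEDLLHE(2)SHRM(349)AQKM
TaHsfA2-3	5D	AA1442920	348	38.91	(159)LKRDRQLLM(127)KRRKP(225)RKELEDAISNKRRRRID(315)DDFWEDLLHE(344)AEKL
TaHsfA2-4	2A	AA0357000	413	45.61	(130)RRRKP(229)RKELHDAISKKRRRRID(370)DNFWEELLNK
TaHsfA2-5	2B	AA0492290	405	44.93	(131)RRRKP(239)KKRRRR(362)DNFWEGLLNK
TaHsfA2-6	2D	AA0573260	412	45.44	(130)RRRKP(229)RKELHDAISKKRRRRID(369)DNFWEELLNK
TaHsfA2-7	4A	AA1018260	341	39.61	(133)KRRRP(241)PTKRRRP(311)DDFWEELLSE(2)DRVL
TaHsfA2-8	4B	AA1062420	341	39.6	(133)KRRR(241)PTKRRRP(311)DDFWEELLSE(2)DRVL
TaHsfA2-9	4D	AA1126990	341	39.5	(133)KRRRP(243)KRRR(311)DDFWEELLSE
TaHsfA2-10	5A	AA1256510	372	41.14	(320)LLSLGLE(153)RRRR(259)RRKELAEALLSKKRGRP(314)ESFWKELLSL
TaHsfA2-11	U	NA	373	41.44	(322)LLSLGLE(153)RRRRP(261)RRKELADALLSKKRGRP(314)ESFWKELLSL
TaHsfA2-12	5D	AA1405180	377	41.6	(326)LLSLGLE(153)RRRRP(261)RRKELAEALLSKKRGRP(320)ESFWKELLSL
TaHsfA2-13	1A	AA0048030	364	41.03	(166)IDRLKRDKNLLI(135)KRRKP(234)KRKELEDAISKKRRRPI(318)NDFWAELFSD
TaHsfA2-14	1B	AA0114190	364	41.03	(166)IDRLKRDKNLLI(135)KRRKP(234)KRKELEDAISKKRRRPI(318)NDFWAELFSD
TaHsfA2-15	1D	AA0199110	370	42.05	(172)IDRLKRDKNLLI(141)KRRKP(240)KRKELEDAISKKRRRPI(324)NDFWAELFSD
TaHsfA2-16	3A	AA0636800	397	44.24	(129)RRRRP(237)KKRRR(354)DDFWEELMSR
TaHsfA2-17	3B	AA0745290	433	48.01	(128)RRRRP(236)KKRRR(353)DDFWEELMSR
TaHsfA2-18	3D	NA	407	46.23	(369)LDVYKLDL(81)RRRRP(189)KKRRR(353)RRRH(306)DDFWEELMSR
TaHsfA3-1	2A	AA0373860	467	51.63	(438)FDALDDGDLHL(402)DTFFQSSCSG(463)GNMK
TaHsfA3-2	2A	AA0367680	502	55.45	(437)DTFFQSSCSG(498)GNMK
TaHsfA3-3	2B	AA0455720	475	52.09	(29)LEPKLEM(433)DTFFQSSCSG
TaHsfA3-4	2D	AA0576700	499	54.79	(25)LLLEPKLEM(47)EALDDGDLHL(434)DTFFQSSCSG(495)GNMK
TaHsfA4-1	1A	AA0026630	443	49.57	(263)MELALVSM(112)HRRKP(220)KKRR(386)DLFWERFLTD(439)SAQK
TaHsfA4-2	1B	AA0108940	445	49.88	(263)MELALVSM(110)HRRKP(219)KKRR(388)DLFWERFLTD(441)SAQK
TaHsfA4-3	1D	AA0193800	442	49.71	(266)MELALVSM(110)HRRKP(218)KKRR(385)DLFWERFLTD(438)SAQK
TaHsfA4-4	3A	AA0661360	432	48.38	(133)LKCDNASLKL(100)HRRKP(198)KKRR(370)DGFWQQFLTE(428)SAEK
TaHsfA4-5	3B	AA0790580	441	49.47	(133)LKCDNASLKL(100)HRRKP(198)KKRR(379)DGFWQQFLTE(437)SAEK
TaHsfA4-6	3D	AA0847210	433	48.46	(133)LKCDNASLNL(100)HRRKP(198)KKRR(370)DGFWQQFLTE(429)SAEK
TaHsfA5-1	6A	AA1567660	458	49.88	(340)LTL(109)RRKP(212)HKKRR(414)DNFWEQFLTE(454)EQLK
TaHsfA5-2	6B	AA1650270	455	49.93	(340)LTL(109)RRKP(212)HKKRR(414)DNFWEQFLTE(451)EQLK
TaHsfA5-3	6D	AA1745290	458	49.87	(340)LTL(109)RRKP(212)HKKRR(414)DNFWEQFLTE(454)EQLK
TaHsfA6-1	7A	AA1799040	310	33.78	(202)KKKRR(247)DMIWYELLEE
TaHsfA6-2	7B	AA1908250	351	37.9	(136)RRRR(250)KKKRR(299)DMIWYELLEE
TaHsfA6-3	7D	AA2004680	351	37.98	(136)RRRR(250)KKKRR(299)DMIWYELLEE
TaHsfA9-1	4A	AA1009080	383	42.86	(165)LKRDKSLLMQQL(124)KRKKRP(242)KKRR(336)MHLWFGEDGE
TaHsfA9-2	4B	AA1071190	384	42.88	(172)LMKQLVDLRL(124)KRKKRP(232)RRNNCVYEDGNKKRRFP(337)MHLWFNEDGE
TaHsfA9-3	4D	AA1142510	384	42.93	(172)LMKQLVDLRL(124)KRKKRP(232)RRNNCVYEDGNKKRRFP(337)MHLWFSEDGE
TaHsfB1-1	5A	AA1196580	298	32.15	(209)LDVRQLDLRLLM(114)RRRK(103)RRGEQGLLSGIRRRKAT
TaHsfB1-2	5B	AA1307960	298	32.29	(211)LDVRQLDLRLLM(117)RRRK(106)RRGEQSLLSGIRRRKAT
TaHsfB1-3	5D	AA1418380	298	32.06	(211)LDVRQLDLRLLM(117)RRRK(106)RRGEQSLLSGIRRRKAT
TaHsfB2-1	2A	AA0301090	295	31.99	(262)MRTERSDLNVLSL(89)RKGEKRLLGAIQRRKGS(165)RRENARLARELARARRV
TaHsfB2-2	2D	AA2166870	209	22.73	(102)RKGEKRLLGAIQRRKGS(178)RRENARLARELARARRV
TaHsfB2-3	7A	AA1829250	374	40.46	(119)HRRK(108)RRGEKRLLCDIHRRKVT
TaHsfB2-4	7B	AA1935670	374	40.34	(119)HRRK(108)RRGEKRLLCDIHRRKVT
TaHsfB2-5	7D	AA2015840	367	39.79	(119)HRRK(108)RRGEKRLLCDIHRRKVT
TaHsfB2-6	5A	AA0058470	404	42.04	(129)HRRK(118)RRGEKRLLCDIHRRKVV
TaHsfB2-7	5B	AA1315570	701	73.93	(78)LLPLGISLVI(252)RRGEKRLLCDIHRRKVV(668)RRRP
TaHsfB2-8	5D	AA1415650	397	41.11	(129)HRRK(118)RRGEKRLLCDIHRRKVV
TaHsfB4-1	2A	AA2122890	320	35.26	(269)LELDMDV(115)RKGAKHLLAEIHRRKSS(299)KKKR
TaHsfB4-2	2D	AA0597540	320	35.32	(269)LELDMDV(116)RKGAKHLLAEIHRRKSS(299)KKKR
TaHsfB4-3	5A	AA1189330	388	41.36	(362)LALENPDLSL(103)RKGEKQLLCEIHRRKTS(6)ERCG
TaHsfB4-4	5B	AA1293070	388	41.46	(362)LALENPDLSL(103)RKGEKQLLCEIHRRKTS(6)ERCG
TaHsfB4-5	5D	AA1418740	388	41.4	(362)LALENPDLSL(103)RKGEKQLLCEIHRRKTS(2)ERCG
TaHsfC1-1	3A	AA0634640	294	32.58	(78)PRIVRRK
TaHsfC1-2	3B	AA0722380	325	35.73	(10)LGLI(109)PRIVRRK
TaHsfC1-3	3D	AA0860000	321	35.39	(10)LGLI(109)PRIVRRK
TaHsfC1-4	3A	AA0670400	277	31.16	(175)LQQAAEKKLQRMHL
TaHsfC1-5	3B	AA0722680	304	33.89	(105)PRIVRRK
TaHsfC1-6	3D	AA0849120	225	25.63	(105)PRIVRRK
TaHsfC1-7	3A	AA0614700	236	26.06	(103)PLIVRKK(198)PDKRRRI
TaHsfC1-8	3B	AA0780810	227	24.69	(103)PLIVRKK(203)PDKRRRI
TaHsfC1-9	3D	AA0873000	241	26.41	(103)PLIVRKK(203)PDKRRRI
TaHsfC2-1	5A	AA2086000	268	30	(197)VKRLRLQL(118)KRKPK(162)RRRK
TaHsfC2-2	7A	AA1794130	266	28.23	(168)LAFLLTVV(103)RRGTAVGGGGGGKRKDA(162)RKPK
TaHsfC2-3	7B	AA1874420	244	26.12	(146)LAFLLTI(140)RKPK
TaHsfC2-4	7D	AA2011440	265	28.18	(167)LAFLLTI(101)RRGTAAAAGGGGGKRKD(161)RKPK
TaHsfC3-1	4D	AA1147440	276	30.27	(169)LMLAFLL(107)PRIVRRR(206)KRRRLLLDGEGQVSKKKMR
TaHsfC3-2	5A	AA1225450	274	30.36	(167)LMLAFLL(163)RRPK(204)KRPRLLLDGEAQMGKKK
TaHsfC3-3	4B	AA1034070	257	28.73	(169)LMLAFLL(105)PRIVRRR(199)PARARRPR
TaHsfC3-4	3B	AA0791830	274	29.98	(168)LAFLL(103)PRIVRRR(203)KRPRLLLDGEVQVGKKK
TaHsfC3-5	3B	AA0777840	230	25.57	(170)LAFLL(108)PRIVRRR(202)KRPR
TaHsfC3-6	4B	AA1034080	257	28.5	(207)LLLNGEVQM(104)PRIVRRR(203)KKPR
TaHsfC3-7	4B	AA1067170	268	30	(158)RRPK
TaHsfC3-8	4B	AA1045990	273	29.46	(174)LLKV(165)RRPK(205)KRPR
TaHsfC3-9	U	AA1138930	276	29.86	(177)LAFLL(171)RRPK(211)KRPR
TaHsfC3-10	5A	AA1241720	273	30.18	(173)RRPK
TaHsfC3-11	U	AA1138960	248	26.43	(141)RRPK(173)KRPR
TaHsfC3-12	3B	AA0830650	237	26.13	(133)LAFLL(127)RRPK(168)KRPR
TaHsfC3-13	4B	AA1040480	248	26.15	(145)RRPK
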