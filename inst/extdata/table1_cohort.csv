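sample_id,sex,alleles,status,dna_conc,mca_reported,ce_reported
001,M,29,NL,25,Neg,n.d.
002,M,31,NL,25,Neg,n.d.
003,M,30,NL,25,Neg,n.d.
004,M,37,NL,25,Neg,n.d.
005,M,35,NL,25,Neg,n.d.
006,M,39,NL,25,Neg,n.d.
007,M,30,NL,25,Neg,n.d.
008,F,30;30,NL,25,Neg,n.d.
009,F,30;30,NL,25,Neg,n.d.
010,F,30;30,NL,25,Neg,n.d.
011,F,30;30,NL,25,Neg,n.d.
012,M,22,NL,25,Neg,n.d.
013,M,31,NL,25,Neg,n.d.
014,M,31,NL,25,Neg,n.d.
015,M,31,NL,25,Neg,n.d.
016,M,29,NL,25,Neg,n.d.
017,F,28;30,NL,25,Neg,n.d.
018,F,31;31,NL,25,Neg,n.d.
019,M,31,NL,25,Neg,n.d.
021,F,31;31,NL,25,Neg,n.d.
022,M,35,NL,25,Neg,n.d.
023,F,30;39,NL,25,Neg,n.d.
024,F,29;32,NL,25,Neg,n.d.
025,F,31;31,NL,25,Neg,30/35
026,M,31,NL,25,Neg,n.d.
027,M,31,NL,25,Neg,n.d.
028,F,29;29,NL,25,Neg,n.d.
029,M,36,NL,25,Neg,n.d.
030,M,29,NL,25,Neg,n.d.
031,M,30,NL,25,Neg,n.d.
032,M,38,NL,25,Neg,n.d.
033,F,30;30,NL,25,Neg,n.d.
034,M,30,NL,25,Neg,n.d.
035,M,30,NL,25,Neg,n.d.
037,M,32,NL,25,Neg,n.d.
038,M,30,NL,25,Neg,n.d.
039,F,29;29,NL,25,Neg,n.d.
040,F,30;30,NL,25,Neg,n.d.
041,F,30;30,NL,25,Neg,n.d.
042,M,37,NL,25,Neg,n.d.
043,F,31;32,NL,25,Neg,n.d.
044,M,545,FM,25,Pos,> 200
045,F,28;30,NL,25,Neg,n.d.
046,M,31,NL,25,Neg,n.d.
049,F,29;29,NL,25,Neg,n.d.
051,M,31,NL,25,Neg,n.d.
052,F,40;40,NL,25,Neg,39/44
053,F,30;30,NL,25,Neg,n.d.
054,M,29;51,NL,25,Neg,n.d.
055,F,29;30,NL,25,Neg,n.d.
056,M,31,NL,25,Neg,n.d.
057,F,30;36,NL,25,Neg,n.d.
058,M,30,NL,25,Neg,n.d.
059,F,28;28,NL,25,Neg,n.d.
060,M,29,NL,25,Neg,n.d.
061,F,20;20,NL,25,Neg,n.d.
062,F,27;35,NL,25,Neg,n.d.
063,F,29;29,NL,25,Neg,n.d.
064,F,29;36,NL,25,Neg,n.d.
065,M,30,NL,25,Neg,n.d.
066,M,28,NL,25,Neg,n.d.
067,F,29;36,NL,25,Neg,n.d.
068,F,24;26,NL,25,Neg,n.d.
069,M,26,NL,25,Neg,n.d.
070,M,33,NL,25,Neg,n.d.
071,F,26;26,NL,25,Neg,n.d.
072,M,37,NL,25,Neg,n.d.
073,M,27,NL,25,Neg,n.d.
074,M,26,NL,25,Neg,n.d.
075,F,27;34,NL,25,Neg,n.d.
076,M,28,NL,25,Neg,n.d.
077,M,28,NL,25,Neg,n.d.
078,M,28,NL,25,Neg,n.d.
079,M,29,NL,25,Neg,n.d.
080,F,28;28,NL,25,Neg,n.d.
081,F,30;30,NL,25,Neg,n.d.
082,M,29,NL,25,Neg,n.d.
083,M,30,NL,25,Neg,n.d.
084,F,30;30,NL,25,Neg,n.d.
085,M,29,NL,25,Neg,n.d.
086,F,29;29,NL,25,Neg,n.d.
087,M,36,NL,25,Neg,36
088,F,28;28,NL,25,Neg,n.d.
089,F,28;28,NL,25,Neg,n.d.
090,M,29,NL,25,Neg,n.d.
091,M,30,NL,25,Neg,n.d.
092,F,28;28,NL,25,Neg,n.d.
093,F,27;27,NL,25,Neg,n.d.
094,F,30;30,NL,25,Neg,n.d.
095,M,20,NL,25,Neg,n.d.
096,M,29,NL,25,Neg,n.d.
097,M,21,NL,25,Neg,n.d.
098,F,28;35,NL,25,Neg,n.d.
099,F,28;35,NL,25,Neg,n.d.
100,F,28;40,NL,25,Neg,29/41
101,F,27;27,NL,25,Neg,n.d.
102,M,27,NL,25,Neg,n.d.
103,M,26,NL,25,Neg,29
104,F,27;27,NL,25,Neg,29
105,F,25;25,NL,25,Neg,n.d.
106,M,28,NL,25,Neg,n.d.
107,M,30,NL,25,Neg,30
113,F,29;29,NL,25,Neg,29/30
114,M,110,PM,8,Pos,"∼100,115,125"
125,M,29,NL,25,Neg,n.d.
126,M,30,NL,25,Neg,n.d.
127,M,23,NL,25,Neg,n.d.
128,M,30,NL,25,Neg,30
131,M,29,NL,25,Neg,29
133,M,32,NL,25,Neg,30
136,F,20;28,NL,25,Neg,n.d.
137,F,15;29,NL,25,Neg,n.d.
138,M,31,NL,25,Neg,30
139,F,20;30,NL,25,Neg,n.d.
140,F,28;28,NL,25,Neg,29/30
141,F,28;28,NL,25,Neg,n.d.
142,F,25;30,NL,25,Neg,n.d.
143,F,29;31,NL,25,Neg,n.d.
144,F,30;30,NL,25,Neg,n.d.
145,M,30,NL,1,Neg,28
146,M,10,NL,25,Neg,9
147,F,28;28,NL,25,Neg,29/30
148,M,30,NL,25,Neg,n.d.
149,M,83,PM,25,Pos,∼80
150,F,29;29,NL,25,Neg,n.d.
151,F,22;30,NL,25,Neg,n.d.
152,F,29;128,PM,25,Pos,"29/∼130, > 200"
153,M,29,NL,25,Neg,29
154,F,28;110;222;441;504;900,FM,25,Pos,"29/∼95, > 200"
155,F,29;29,NL,25,Neg,n.d.
156,F,31;31,NL,25,Neg,n.d.
157,F,25;185;324;551;658;800,FM,25,Pos,24/> 200
158,M,30,NL,25,Neg,n.d.
159,F,32;423-850,FM,25,Pos,32/> 200
160,F,24;225,FM,25,Pos,24/> 200
161,F,31;31,NL,25,Neg,n.d.
162,F,29;76,PM,25,Pos,30/∼75
163,M,36,NL,25,Neg,n.d.
164,M,29,NL,25,Neg,29
165,F,28;288;532,FM,25,Pos,29/> 200
166,F,28;223;446;769,FM,25,Pos,29/> 200
167,M,29,NL,25,Neg,n.d.
168,M,29,NL,25,Neg,n.d.
169,F,29;125,PM,25,Pos,"29/∼130,175"
170,F,30;30,NL,25,Neg,n.d.
171,F,34;290,FM,25,Pos,34/> 200
172,F,30;101,PM,25,Pos,"30/∼75,100,120"
210,F,28;28,NL,25,Neg,n.d.
211,M,29,NL,25,Neg,29
212,F,30;150,PM,25,Pos,"30/∼130,135,150,170,180"
213,F,29;29,NL,25,Neg,n.d.
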