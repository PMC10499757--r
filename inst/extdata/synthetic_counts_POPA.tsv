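locus_id	A	C	G	T
synth_001:1000 A>T	9948	0	0	52
synth_002:2000 G>T	0	0	9840	160
synth_003:3000 T>A	80	0	0	9920
synth_004:4000 C>A	34	9966	0	0
synth_005:5000 C>A	47	9953	0	0
synth_006:6000 C>T	0	9831	0	169
synth_007:7000 C>G	0	9802	198	0
synth_008:8000 A>C	9783	217	0	0
synth_009:9000 G>C	0	59	9941	0
synth_010:10000 G>A	194	0	9806	0
synth_011:11000 C>A	162	9838	0	0
synth_012:12000 T>A	55	0	0	9945
synth_013:13000 A>G	9806	0	194	0
synth_014:14000 A>T	9872	0	0	128
synth_015:15000 A>C	9900	100	0	0
synth_016:16000 C>G	0	9879	121	0
synth_017:17000 C>G	0	9925	75	0
synth_018:18000 G>A	63	0	9937	0
synth_019:19000 T>C	0	19	0	9981
synth_020:20000 C>G	0	9807	193	0
synth_021:21000 T>A	31	0	0	9969
synth_022:22000 G>A	183	0	9817	0
synth_023:23000 A>T	9956	0	0	44
synth_024:24000 A>T	9966	0	0	34
synth_025:25000 T>A	86	0	0	9914
synth_026:26000 A>G	9816	0	184	0
synth_027:27000 C>T	0	9938	0	62
synth_028:28000 C>T	0	9978	0	22
synth_029:29000 G>T	0	0	9916	84
synth_030:30000 T>C	0	58	0	9942
synth_031:31000 A>T	9811	0	0	189
synth_032:32000 T>C	0	68	0	9932
synth_033:33000 G>T	0	0	9895	105
synth_034:34000 T>G	0	0	66	9934
synth_035:35000 A>C	9967	33	0	0
synth_036:36000 A>C	9956	44	0	0
synth_037:37000 C>G	0	9837	163	0
synth_038:38000 C>G	0	9923	77	0
synth_039:39000 A>C	9894	106	0	0
synth_040:40000 G>A	182	0	9818	0
synth_041:41000 T>C	0	183	0	9817
synth_042:42000 A>G	9958	0	42	0
synth_043:43000 T>A	92	0	0	9908
synth_044:44000 C>G	0	9914	86	0
synth_045:45000 A>G	9882	0	118	0
synth_046:46000 C>T	0	9812	0	188
synth_047:47000 C>A	169	9831	0	0
synth_048:48000 G>C	0	78	9922	0
synth_049:49000 A>T	9882	0	0	118
synth_050:50000 G>A	81	0	9919	0
synth_051:51000 A>G	9898	0	102	0
synth_052:52000 C>T	0	9906	0	94
synth_053:53000 T>G	0	0	160	9840
synth_054:54000 T>C	0	121	0	9879
synth_055:55000 A>T	9879	0	0	121
synth_056:56000 T>A	103	0	0	9897
synth_057:57000 G>A	152	0	9848	0
synth_058:58000 C>T	0	9884	0	116
synth_059:59000 G>A	153	0	9847	0
synth_060:60000 C>G	0	9924	76	0
synth_061:61000 A>C	9928	72	0	0
synth_062:62000 G>T	0	0	9964	36
synth_063:63000 C>G	0	9808	192	0
synth_064:64000 A>T	9854	0	0	146
synth_065:65000 A>T	9856	0	0	144
synth_066:66000 T>A	25	0	0	9975
synth_067:67000 C>G	0	9891	109	0
synth_068:68000 T>G	0	0	179	9821
synth_069:69000 T>G	0	0	140	9860
synth_070:70000 G>C	0	187	9813	0
synth_071:71000 C>G	0	9977	23	0
synth_072:72000 A>T	9874	0	0	126
synth_073:73000 T>A	116	0	0	9884
synth_074:74000 C>A	163	9837	0	0
synth_075:75000 A>C	9885	115	0	0
synth_076:76000 T>A	134	0	0	9866
synth_077:77000 T>C	0	128	0	9872
synth_078:78000 G>C	0	98	9902	0
synth_079:79000 T>C	0	80	0	9920
synth_080:80000 T>G	0	0	36	9964
synth_081:81000 A>C	9918	82	0	0
synth_082:82000 T>A	193	0	0	9807
synth_083:83000 C>A	101	9899	0	0
synth_084:84000 G>T	0	0	9927	73
synth_085:85000 A>C	9883	117	0	0
synth_086:86000 A>C	9860	140	0	0
synth_087:87000 C>G	0	9858	142	0
synth_088:88000 G>C	0	30	9970	0
synth_089:89000 G>T	0	0	9862	138
synth_090:90000 A>C	9857	143	0	0
synth_091:91000 G>A	31	0	9969	0
synth_092:92000 C>G	0	9786	214	0
synth_093:93000 C>T	0	9862	0	138
synth_094:94000 G>T	0	0	9838	162
synth_095:95000 G>C	0	149	9851	0
synth_096:96000 T>A	181	0	0	9819
synth_097:97000 A>G	9908	0	92	0
synth_098:98000 T>C	0	144	0	9856
synth_099:99000 G>A	110	0	9890	0
synth_100:100000 A>T	9861	0	0	139
synth_101:101000 A>T	9970	0	0	30
synth_102:102000 G>C	0	192	9808	0
synth_103:103000 T>C	0	171	0	9829
synth_104:104000 A>G	9952	0	48	0
synth_105:105000 C>A	162	9838	0	0
synth_106:106000 A>C	9792	208	0	0
synth_107:107000 G>T	0	0	9837	163
synth_108:108000 G>C	0	35	9965	0
synth_109:109000 A>T	9798	0	0	202
synth_110:110000 C>A	146	9854	0	0
synth_111:111000 G>A	21	0	9979	0
synth_112:112000 T>G	0	0	63	9937
synth_113:113000 T>C	0	92	0	9908
synth_114:114000 G>A	54	0	9946	0
synth_115:115000 G>C	0	123	9877	0
synth_116:116000 G>A	177	0	9823	0
synth_117:117000 C>T	0	9915	0	85
synth_118:118000 A>C	9979	21	0	0
synth_119:119000 A>T	9861	0	0	139
synth_120:120000 G>C	0	176	9824	0
synth_121:121000 A>C	9972	28	0	0
synth_122:122000 T>A	112	0	0	9888
synth_123:123000 A>T	9962	0	0	38
synth_124:124000 C>T	0	9940	0	60
synth_125:125000 C>G	0	9852	148	0
synth_126:126000 A>G	9970	0	30	0
synth_127:127000 T>A	156	0	0	9844
synth_128:128000 G>A	100	0	9900	0
synth_129:129000 G>C	0	137	9863	0
synth_130:130000 C>T	0	9818	0	182
synth_131:131000 A>G	9905	0	95	0
synth_132:132000 A>G	9916	0	84	0
synth_133:133000 G>A	39	0	9961	0
synth_134:134000 T>G	0	0	39	9961
synth_135:135000 G>T	0	0	9928	72
synth_136:136000 C>A	197	9803	0	0
synth_137:137000 C>A	93	9907	0	0
synth_138:138000 T>C	0	128	0	9872
synth_139:139000 G>T	0	0	9858	142
synth_140:140000 G>T	0	0	9875	125
synth_141:141000 C>G	0	9876	124	0
synth_142:142000 G>T	0	0	9846	154
synth_143:143000 A>G	9969	0	31	0
synth_144:144000 A>G	9939	0	61	0
synth_145:145000 G>A	81	0	9919	0
synth_146:146000 G>A	165	0	9835	0
synth_147:147000 A>G	9899	0	101	0
synth_148:148000 C>G	0	9842	158	0
synth_149:149000 G>A	162	0	9838	0
synth_150:150000 T>C	0	175	0	9825
synth_151:151000 T>A	77	0	0	9923
synth_152:152000 A>T	9875	0	0	125
synth_153:153000 A>C	9822	178	0	0
synth_154:154000 G>T	0	0	9911	89
synth_155:155000 T>A	126	0	0	9874
synth_156:156000 T>G	0	0	120	9880
synth_157:157000 T>A	110	0	0	9890
synth_158:158000 G>C	0	98	9902	0
synth_159:159000 A>G	9828	0	172	0
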