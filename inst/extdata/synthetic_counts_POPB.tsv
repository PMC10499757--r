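locus_id	A	C	G	T
synth_001:1000 A>T	99965	0	0	35
synth_002:2000 G>T	0	0	99830	170
synth_003:3000 T>A	78	0	0	99922
synth_004:4000 C>A	38	99962	0	0
synth_005:5000 C>A	154	99846	0	0
synth_006:6000 C>T	0	99984	0	16
synth_007:7000 C>G	0	99982	18	0
synth_008:8000 A>C	99994	6	0	0
synth_009:9000 G>C	0	146	99854	0
synth_010:10000 G>A	56	0	99944	0
synth_011:11000 C>A	107	99893	0	0
synth_012:12000 T>A	51	0	0	99949
synth_013:13000 A>G	99817	0	183	0
synth_014:14000 A>T	99934	0	0	66
synth_015:15000 A>C	99918	82	0	0
synth_016:16000 C>G	0	99977	23	0
synth_017:17000 C>G	0	99901	99	0
synth_018:18000 G>A	31	0	99969	0
synth_019:19000 T>C	0	157	0	99843
synth_020:20000 C>G	0	99861	139	0
synth_021:21000 T>A	8	0	0	99992
synth_022:22000 G>A	59	0	99941	0
synth_023:23000 A>T	99843	0	0	157
synth_024:24000 A>T	99940	0	0	60
synth_025:25000 T>A	102	0	0	99898
synth_026:26000 A>G	99928	0	72	0
synth_027:27000 C>T	0	99863	0	137
synth_028:28000 C>T	0	99854	0	146
synth_029:29000 G>T	0	0	99938	62
synth_030:30000 T>C	0	100	0	99900
synth_031:31000 A>T	99925	0	0	75
synth_032:32000 T>C	0	84	0	99916
synth_033:33000 G>T	0	0	99963	37
synth_034:34000 T>G	0	0	78	99922
synth_035:35000 A>C	99795	205	0	0
synth_036:36000 A>C	99987	13	0	0
synth_037:37000 C>G	0	99902	98	0
synth_038:38000 C>G	0	99935	65	0
synth_039:39000 A>C	99880	120	0	0
synth_040:40000 G>A	181	0	99819	0
synth_041:41000 T>C	0	184	0	99816
synth_042:42000 A>G	99948	0	52	0
synth_043:43000 T>A	14	0	0	99986
synth_044:44000 C>G	0	99837	163	0
synth_045:45000 A>G	99848	0	152	0
synth_046:46000 C>T	0	99861	0	139
synth_047:47000 C>A	175	99825	0	0
synth_048:48000 G>C	0	126	99874	0
synth_049:49000 A>T	99882	0	0	118
synth_050:50000 G>A	139	0	99861	0
synth_051:51000 A>G	99852	0	148	0
synth_052:52000 C>T	0	99883	0	117
synth_053:53000 T>G	0	0	46	99954
synth_054:54000 T>C	0	118	0	99882
synth_055:55000 A>T	99819	0	0	181
synth_056:56000 T>A	178	0	0	99822
synth_057:57000 G>A	196	0	99804	0
synth_058:58000 C>T	0	99941	0	59
synth_059:59000 G>A	70	0	99930	0
synth_060:60000 C>G	0	99873	127	0
synth_061:61000 A>C	99934	66	0	0
synth_062:62000 G>T	0	0	99850	150
synth_063:63000 C>G	0	99918	82	0
synth_064:64000 A>T	99820	0	0	180
synth_065:65000 A>T	99774	0	0	226
synth_066:66000 T>A	110	0	0	99890
synth_067:67000 C>G	0	99921	79	0
synth_068:68000 T>G	0	0	130	99870
synth_069:69000 T>G	0	0	54	99946
synth_070:70000 G>C	0	138	99862	0
synth_071:71000 C>G	0	99920	80	0
synth_072:72000 A>T	99870	0	0	130
synth_073:73000 T>A	166	0	0	99834
synth_074:74000 C>A	101	99899	0	0
synth_075:75000 A>C	99856	144	0	0
synth_076:76000 T>A	90	0	0	99910
synth_077:77000 T>C	0	95	0	99905
synth_078:78000 G>C	0	44	99956	0
synth_079:79000 T>C	0	42	0	99958
synth_080:80000 T>G	0	0	114	99886
synth_081:81000 A>C	99935	65	0	0
synth_082:82000 T>A	35	0	0	99965
synth_083:83000 C>A	161	99839	0	0
synth_084:84000 G>T	0	0	99884	116
synth_085:85000 A>C	99831	169	0	0
synth_086:86000 A>C	99814	186	0	0
synth_087:87000 C>G	0	99833	167	0
synth_088:88000 G>C	0	34	99966	0
synth_089:89000 G>T	0	0	99912	88
synth_090:90000 A>C	99875	125	0	0
synth_091:91000 G>A	198	0	99802	0
synth_092:92000 C>G	0	99943	57	0
synth_093:93000 C>T	0	99930	0	70
synth_094:94000 G>T	0	0	99800	200
synth_095:95000 G>C	0	158	99842	0
synth_096:96000 T>A	178	0	0	99822
synth_097:97000 A>G	99897	0	103	0
synth_098:98000 T>C	0	98	0	99902
synth_099:99000 G>A	64	0	99936	0
synth_100:100000 A>T	99819	0	0	181
synth_101:101000 A>T	99807	0	0	193
synth_102:102000 G>C	0	132	99868	0
synth_103:103000 T>C	0	59	0	99941
synth_104:104000 A>G	99951	0	49	0
synth_105:105000 C>A	182	99818	0	0
synth_106:106000 A>C	99904	96	0	0
synth_107:107000 G>T	0	0	99946	54
synth_108:108000 G>C	0	178	99822	0
synth_109:109000 A>T	99973	0	0	27
synth_110:110000 C>A	111	99889	0	0
synth_111:111000 G>A	94	0	99906	0
synth_112:112000 T>G	0	0	75	99925
synth_113:113000 T>C	0	158	0	99842
synth_114:114000 G>A	56	0	99944	0
synth_115:115000 G>C	0	92	99908	0
synth_116:116000 G>A	74	0	99926	0
synth_117:117000 C>T	0	99994	0	6
synth_118:118000 A>C	99888	112	0	0
synth_119:119000 A>T	99972	0	0	28
synth_120:120000 G>C	0	33	99967	0
synth_121:121000 A>C	99790	210	0	0
synth_122:122000 T>A	30	0	0	99970
synth_123:123000 A>T	99971	0	0	29
synth_124:124000 C>T	0	99869	0	131
synth_125:125000 C>G	0	99949	51	0
synth_126:126000 A>G	99838	0	162	0
synth_127:127000 T>A	154	0	0	99846
synth_128:128000 G>A	8	0	99992	0
synth_129:129000 G>C	0	38	99962	0
synth_130:130000 C>T	0	99890	0	110
synth_131:131000 A>G	99928	0	72	0
synth_132:132000 A>G	99809	0	191	0
synth_133:133000 G>A	206	0	99794	0
synth_134:134000 T>G	0	0	147	99853
synth_135:135000 G>T	0	0	99910	90
synth_136:136000 C>A	63	99937	0	0
synth_137:137000 C>A	47	99953	0	0
synth_138:138000 T>C	0	79	0	99921
synth_139:139000 G>T	0	0	99798	202
synth_140:140000 G>T	0	0	99831	169
synth_141:141000 C>G	0	99860	140	0
synth_142:142000 G>T	0	0	99972	28
synth_143:143000 A>G	99977	0	23	0
synth_144:144000 A>G	1e+05	0	0	0
synth_145:145000 G>A	57	0	99943	0
synth_146:146000 G>A	73	0	99927	0
synth_147:147000 A>G	99912	0	88	0
synth_148:148000 C>G	0	99784	216	0
synth_149:149000 G>A	36	0	99964	0
synth_150:150000 T>C	0	150	0	99850
synth_151:151000 T>A	61	0	0	99939
synth_152:152000 A>T	99806	0	0	194
synth_153:153000 A>C	99965	35	0	0
synth_154:154000 G>T	0	0	99996	4
synth_155:155000 T>A	0	0	0	1e+05
synth_156:156000 T>G	0	0	139	99861
synth_157:157000 T>A	0	0	0	1e+05
synth_158:158000 G>C	0	84	99916	0
synth_159:159000 A>G	99848	0	152	0
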