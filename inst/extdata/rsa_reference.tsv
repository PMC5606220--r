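one_letter	all_atoms_abs	total_side_abs	main_chain_abs	non_polar_abs	all_polar_abs
A	111.593432	66.576946	45.016486	75.586077	36.007355
C	141.398160	98.106972	43.291189	42.365304	99.032856
D	151.311920	108.344636	42.967283	59.192251	92.119669
E	181.381791	138.346469	43.035323	74.300155	107.081636
F	217.038015	177.111609	39.926406	183.397929	33.640086
G	85.905212	0.000000	85.905212	42.508788	43.396424
H	194.559027	155.211747	39.347280	119.900735	74.658293
I	180.357179	140.667316	39.689863	145.761906	34.595273
K	212.357941	169.324254	43.033687	119.281190	93.076751
L	184.749281	144.852688	39.896594	149.619290	35.129992
M	202.083143	158.975611	43.107532	124.422897	77.660247
N	158.574212	115.605880	42.968333	50.046848	108.527364
P	137.053652	95.033804	42.019848	105.266584	31.787068
Q	188.119000	145.012481	43.106519	64.782232	123.336768
R	243.900705	209.401615	34.499090	97.985229	145.915476
S	122.493379	77.943931	44.549448	52.161152	70.332227
T	143.027209	105.111179	37.916030	84.695420	58.331789
V	152.354365	120.688261	31.666104	128.325614	24.028751
W	261.167698	222.506099	38.661599	206.335974	54.831723
Y	227.486234	187.571358	39.914876	154.312095	73.174139
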