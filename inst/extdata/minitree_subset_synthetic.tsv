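node_name	parent_name	motif
rCRS		
L3	rCRS	16126T 225C 1838G
M	L3	16089A 164T 5837G
D	M	16344G 2415C
D4	D	16211T 6344C
G	M	16165G 14968T
G2a	G	16159C 13845A
M7	M	16192T 8425A
M7b	M7	16331C 1226C
M8	M	16271C 6516G
C	M8	16083T 3442G
C4	C	16282G 8888C
Z	M8	16086G 12202A
Z1	Z	16262C 9839G
M9	M	16349G 10649T
M9a	M9	16327G 9306G
M10	M	16087C 8931G
A	L3	16266G 236A 3853C
A4	A	16346A 15809C
N1	L3	16253C 16429G 10224G
I	N1	16161C 4624G
I1	I	16133C 3743T
I1c	I1	16142G 8695T
I4	I	16186G 12457C
N1a	N1	16272C 9156G
N2	L3	16357T 179T 7397A
W	N2	16065C 4945G
W1	W	16149C 15415C
N9	L3	16073C 400G 13670G
Y	N9	16032T 15339G
Y1	Y	16203G 11894T
N9a	N9	16048T 865C
X	L3	16169A 561G 1312T
X2	X	16130T 1649G
X2b	X2	16275G 721G
R	L3	16355A 344C 12160G
B	R	16288G 2480C
B4	B	16296T 2825G
R9	R	16359A 2108C
F	R9	16229A 3844G
F1b	F	16321T 6122G
R11	R	16059C 4896T
JT	R	16026G 159A 12153T
J	JT	16113T 9790G
T	JT	16117G 6676G
J1b	J	16127C 9847C
J1b1	J1b	16110C 2698G
J1b1b1	J1b1	16029C 5383T
J1b2	J1b	16042G 3553T
J1d	J	16181G 14403C
J1d6	J1d	16277A 1736G
T1	T	16216C 6646A
T1a	T1	16195C 3850A
T2	T	16153C 9976T
T2g	T2	16214G 8230G
T2g1a	T2g	16107G 12910G
R0	R	16075T 183C 1853T
HV	R0	16226T 4176A
H	HV	16095T 8998A
V	HV	16171T 1558T
V1	V	16134T 12217C
H1	H	16307A 11190T
H1b	H1	16179C 8292T
H1c	H1	16178T 10648G
H1j	H1	16309G 898C
H5	H	16160T 12966T
H5a	H5	16131A 2329A
H5a1	H5a	16143A 12257G
HV13	HV	16150T 5206T
HV13b	HV13	16039A 5701T
HV13b1	HV13b	1654G 9377T 11152A 16184A 16291C
U	R	16269T 511C 1147T
U2	U	16050A 2499A
U2e	U2	16175A 5938T
U2e1	U2e	16102T 5452C
U2e1a	U2e1	16182A 9654G
U2e1a1	U2e1a	16163G 15673A
U2e1b	U2e1	16025T 3545G
U4	U	16120T 10045T
U4b	U4	16280A 12976T
U4b1a	U4b	16323C 11967G
U4b1a1	U4b1a	16128A 11196T
U4b1a1a	U4b1a1	16088C 12836C
U4b1a1a1	U4b1a1a	16350G 8074C
U4b1a4	U4b1a	16118T 1859G
U4d	U4	16125G 2384A
U4d2	U4d	16209G 14164T
U5	U	16224T 12560C
U5a	U5	16258C 5071G
U5a1	U5a	16064G 3392G
U5b	U5	16080G 12522G
U5b1	U5b	16188C 12358T
U5b1c	U5b1	16036T 9059T
U5b1c2	U5b1c	9110G
U8	U	16100G 3443C
U8b	U8	16101G 6112C
U8b1a	U8b	16109G 14942C
U8b1a1	U8b1a	16352G 13946G
K	U8b	16124T 9089A
K1	K	16237G 5746G
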