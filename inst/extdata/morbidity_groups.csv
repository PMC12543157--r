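icd_prefix,item_label
A,4b
B,4b
C,8e
D,8e
D50,8d
D51,8d
D52,8d
D53,8d
D54,8d
D55,8d
D56,8d
D57,8d
D58,8d
D59,8d
D60,8d
D61,8d
D62,8d
D63,8d
D64,8d
E,8e
E10,7b
E11,7b
E12,7b
E13,7b
E14,7b
F,8e
G,8e
H,8e
I,8c
J,8a
K,8b
L,8e
M,8e
N,8e
O00,1b
O01,1b
O02,1b
O03,1b
O034,1a
O039,1a
O04,1b
O044,1a
O049,1a
O05,1b
O054,1a
O059,1a
O06,1b
O064,1a
O069,1a
O07,1b
O074,1a
O079,1a
O08,1b
O09,11
O10,2b
O11,2b
O12,2a
O13,2a
O14,2a
O15,2a
O16,2a
O20,3
O21,5
O22,5
O23,4a
O24,7b
O244,7a
O25,5
O26,5
O27,5
O28,11
O29,5
O30,11
O31,11
O32,11
O33,11
O34,11
O35,11
O36,11
O37,5
O38,5
O39,5
O40,11
O41,5
O411,4a
O42,11
O43,11
O44,3
O45,3
O46,3
O47,11
O48,11
O49,5
O50,5
O51,5
O52,5
O53,5
O54,5
O55,5
O56,5
O57,5
O58,5
O59,5
O60,5
O61,5
O62,5
O63,5
O64,5
O65,5
O66,5
O67,3
O68,5
O69,5
O70,5
O71,5
O72,3
O73,5
O74,5
O75,5
O753,4a
O80,10
O81,10
O82,10
O83,10
O84,10
O85,4a
O86,4a
O91,4a
O98,8e
O99,8e
O990,8d
O994,8c
O995,8a
O996,8b
R,13
R95,9
R96,9
R97,9
R98,9
R99,9
S,12
T,12
V,12
W,12
X,12
Y,12
Z34,11
Z35,11
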