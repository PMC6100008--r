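{
"acetanilide": {
"KR004": [
[
4
]
],
"KR007": [
[
5,
6,
7,
8,
9,
10
]
],
"KR013": [
[
2,
3
]
],
"KR014": [
[
2,
3,
4
]
],
"KR017": [
[
1
]
],
"KR031": [
[
4,
5
]
],
"KR033": [
[
5
]
],
"KR042": [
[
2,
3,
4
]
]
},
"acrolein": {
"KR013": [
[
3,
4
]
],
"KR029": [
[
1,
2
]
]
},
"arylpiperazine_big": {
"KR005": [
[
7
],
[
10
]
],
"KR007": [
[
2,
3,
4,
5,
19,
20
]
],
"KR008": [
[
13,
14,
15,
16,
17,
18
]
],
"KR010": [
[
14
]
],
"KR018": [
[
6
],
[
8
],
[
9
],
[
11
],
[
12
]
],
"KR021": [
[
1
]
],
"KR022": [
[
1,
2,
3,
4,
5,
19,
20
]
],
"KR031": [
[
10,
13
]
],
"KR033": [
[
2
],
[
5
],
[
13
]
],
"KR034": [
[
8
],
[
9
],
[
11
],
[
12
]
],
"KR035": [
[
7
],
[
10
]
],
"KR038": [
[
7,
8,
9,
10,
11,
12
]
],
"KR039": [
[
6,
7
],
[
7,
8
],
[
7,
12
],
[
9,
10
],
[
10,
11
]
],
"KR041": [
[
5,
6
]
]
},
"benzamide": {
"KR003": [
[
1
]
],
"KR007": [
[
4,
5,
6,
7,
8,
9
]
],
"KR013": [
[
2,
3
]
],
"KR014": [
[
1,
2,
3
]
],
"KR033": [
[
4
]
],
"KR042": [
[
1,
2,
3
]
]
},
"benzene": {
"KR007": [
[
1,
2,
3,
4,
5,
6
]
]
},
"benzonitrile": {
"KR007": [
[
3,
4,
5,
6,
7,
8
]
],
"KR028": [
[
1,
2
]
],
"KR033": [
[
3
]
]
},
"chlorobenzene": {
"KR007": [
[
1,
2,
3,
4,
6,
7
]
],
"KR021": [
[
5
]
],
"KR022": [
[
1,
2,
3,
4,
5,
6,
7
]
],
"KR033": [
[
4
]
]
},
"ethanol": {
"KR001": [
[
3
]
],
"KR017": [
[
1
]
],
"KR018": [
[
2
]
],
"KR040": [
[
2,
3
]
]
},
"ethanolamine": {
"KR001": [
[
1
]
],
"KR003": [
[
4
]
],
"KR018": [
[
2
],
[
3
]
],
"KR039": [
[
3,
4
]
],
"KR040": [
[
1,
2
]
]
},
"furan": {
"KR012": [
[
1,
2,
3,
4,
5
]
]
},
"histidine_like": {
"KR001": [
[
3
]
],
"KR009": [
[
8
]
],
"KR010": [
[
10
]
],
"KR013": [
[
1,
2
]
],
"KR015": [
[
1,
2,
3
]
],
"KR018": [
[
4
],
[
5
]
],
"KR033": [
[
6
]
],
"KR041": [
[
5,
6
]
]
},
"hydroxybenzoic": {
"KR001": [
[
1
],
[
8
]
],
"KR007": [
[
4,
5,
6,
7,
9,
10
]
],
"KR013": [
[
2,
3
]
],
"KR015": [
[
1,
2,
3
]
],
"KR032": [
[
7,
8
]
],
"KR033": [
[
4
],
[
7
]
]
},
"ibuprofen": {
"KR001": [
[
15
]
],
"KR007": [
[
5,
6,
7,
8,
9,
10
]
],
"KR013": [
[
13,
14
]
],
"KR015": [
[
13,
14,
15
]
],
"KR017": [
[
1
],
[
3
],
[
12
]
],
"KR018": [
[
4
]
],
"KR019": [
[
2
],
[
11
]
],
"KR033": [
[
5
],
[
8
]
],
"KR041": [
[
4,
5
],
[
8,
11
]
]
},
"imine": {
"KR007": [
[
4,
5,
6,
7,
8,
9
]
],
"KR017": [
[
1
]
],
"KR030": [
[
2,
3
]
],
"KR033": [
[
4
]
]
},
"indole": {
"KR007": [
[
1,
2,
3,
4,
8,
9
]
],
"KR009": [
[
5
]
],
"KR033": [
[
4
],
[
8
]
]
},
"methanesulfonamide": {
"KR003": [
[
5
]
],
"KR017": [
[
1
]
],
"KR027": [
[
2,
3,
4
]
]
},
"methoxyphenethylamine": {
"KR002": [
[
2
]
],
"KR003": [
[
9
]
],
"KR007": [
[
3,
4,
5,
6,
10,
11
]
],
"KR017": [
[
1
]
],
"KR018": [
[
7
],
[
8
]
],
"KR033": [
[
3
],
[
6
]
],
"KR039": [
[
8,
9
]
],
"KR040": [
[
1,
2
]
],
"KR041": [
[
6,
7
]
]
},
"naphthalene": {
"KR007": [
[
1,
2,
3,
4,
9,
10
],
[
4,
5,
6,
7,
8,
9
]
],
"KR033": [
[
4
],
[
9
]
]
},
"phenylpiperazine": {
"KR005": [
[
2
],
[
5
]
],
"KR007": [
[
6,
7,
8,
9,
10,
11
]
],
"KR017": [
[
1
]
],
"KR018": [
[
3
],
[
4
],
[
12
],
[
13
]
],
"KR031": [
[
5,
6
]
],
"KR033": [
[
6
]
],
"KR034": [
[
3
],
[
4
],
[
12
],
[
13
]
],
"KR035": [
[
2
],
[
5
]
],
"KR038": [
[
2,
3,
4,
5,
12,
13
]
],
"KR039": [
[
1,
2
],
[
2,
3
],
[
2,
13
],
[
4,
5
],
[
5,
12
]
]
},
"piperidine": {
"KR004": [
[
4
]
],
"KR018": [
[
1
],
[
2
],
[
3
],
[
5
],
[
6
]
],
"KR034": [
[
1
],
[
2
],
[
3
],
[
5
],
[
6
]
],
"KR035": [
[
4
]
],
"KR037": [
[
1,
2,
3,
4,
5,
6
]
],
"KR039": [
[
3,
4
],
[
4,
5
]
]
},
"protonated_ethanolamine": {
"KR001": [
[
4
]
],
"KR006": [
[
1
]
],
"KR018": [
[
2
],
[
3
]
],
"KR040": [
[
3,
4
]
]
},
"pyridine": {
"KR008": [
[
1,
2,
3,
4,
5,
6
]
],
"KR010": [
[
4
]
]
},
"pyrrole": {
"KR009": [
[
4
]
]
},
"sugar_like": {
"KR001": [
[
1
],
[
6
],
[
8
],
[
10
],
[
12
]
],
"KR002": [
[
4
]
],
"KR018": [
[
2
]
],
"KR019": [
[
3
],
[
5
],
[
7
],
[
9
],
[
11
]
],
"KR034": [
[
3
],
[
5
],
[
7
],
[
9
],
[
11
]
],
"KR036": [
[
4
]
],
"KR040": [
[
1,
2
],
[
3,
4
],
[
4,
5
],
[
5,
6
],
[
7,
8
],
[
9,
10
],
[
11,
12
]
]
},
"tetramethylammonium": {
"KR006": [
[
2
]
],
"KR017": [
[
1
],
[
3
],
[
4
],
[
5
]
]
},
"thioether": {
"KR017": [
[
1
],
[
4
]
],
"KR018": [
[
2
]
],
"KR026": [
[
3
]
]
},
"thiophene": {
"KR011": [
[
1,
2,
3,
4,
5
]
]
},
"toluene": {
"KR007": [
[
2,
3,
4,
5,
6,
7
]
],
"KR017": [
[
1
]
],
"KR033": [
[
2
]
],
"KR041": [
[
1,
2
]
]
},
"trifluorotoluene": {
"KR007": [
[
5,
6,
7,
8,
9,
10
]
],
"KR020": [
[
2
]
],
"KR021": [
[
1
],
[
3
],
[
4
]
],
"KR024": [
[
1,
2
],
[
2,
3
],
[
2,
4
]
],
"KR025": [
[
1,
2,
3,
4
]
],
"KR033": [
[
5
]
],
"KR041": [
[
2,
5
]
]
},
"tryptamine_like": {
"KR005": [
[
2
]
],
"KR007": [
[
11,
12,
13,
14,
15,
16
]
],
"KR009": [
[
10
]
],
"KR017": [
[
1
]
],
"KR018": [
[
3
],
[
4
],
[
6
],
[
7
]
],
"KR019": [
[
5
]
],
"KR033": [
[
8
],
[
11
],
[
16
]
],
"KR034": [
[
3
],
[
4
],
[
5
],
[
6
],
[
7
]
],
"KR035": [
[
2
]
],
"KR037": [
[
2,
3,
4,
5,
6,
7
]
],
"KR039": [
[
1,
2
],
[
2,
3
],
[
2,
7
]
],
"KR041": [
[
5,
8
]
]
}
}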