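# Functional-category counts of sequences and gene families shared between
# E. coli chromosomes and mobile genetic elements, by identity slice of the
# genome network (100% and 90-99%), from a published 30-strain E. coli
# pangenome survey. One row per COG category letter.
cog_category	n_sequences_100	n_sequences_90_99	n_families_100	n_families_90_99
A	0	0	0	0
B	0	0	0	0
J	28	120	2	4
K	131	255	18	27
L	1838	3670	68	94
D	12	15	1	1
T	82	294	11	24
V	22	148	3	9
Y	0	0	0	0
M	56	295	5	13
N	3	69	1	5
W	0	0	0	0
Z	0	0	0	0
O	0	50	0	4
U	5	94	2	13
C	0	56	0	5
E	6	40	2	6
F	0	28	0	1
G	23	159	6	8
H	49	3	2	1
I	0	13	0	1
P	67	371	4	21
Q	16	56	2	4
R	120	806	19	52
S	138	885	20	45
X	1832	4589	260	356
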