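gene	delta_ct	bestkeeper	normfinder	genorm
GR	1	4	1	4
aaRS	2	3	4	3
PMP-3	3	2	5	1
ArgRS	4	1	6	1
mce1	5	6	2	6
MDH-1	6	5	7	5
AMA-1	7	7	3	7
CSQ-1	8	9	8	9
Y45F10D.4	9	8	9	8
Act-1	10	10	10	10
EIF-3	11	11	11	11
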