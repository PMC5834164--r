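gene	delta_ct	bestkeeper	normfinder	genorm
GR	1	3	1	5
PMP-3	2	7	2	1
AMA-1	3	6	3	4
CSQ-1	4	9	4	3
aaRS	5	10	6	1
MDH-1	6	2	5	8
mce1	7	5	8	6
Y45F10D.4	8	1	7	7
ArgRS	9	8	10	9
EIF-3	10	11	9	10
Act-1	11	4	11	11
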