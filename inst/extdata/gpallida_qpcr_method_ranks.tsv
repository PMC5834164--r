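gene	delta_ct	bestkeeper	normfinder	genorm
AMA-1	1	6	2	1
GR	2	3	1	3
mce1	3	7	5	2
aaRS	4	2	3	6
Y45F10D.4	5	4	6	4
PMP-3	6	1	4	7
MDH-1	7	9	7	5
EIF-3	8	5	8	8
CSQ-1	9	8	9	9
Act-1	10	10	10	10
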