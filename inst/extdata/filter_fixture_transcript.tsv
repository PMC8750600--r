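feature_id	S01	S02	S03	S04	S05	S06	S07	S08	S09	S10	S11	S12	S13	S14	S15
G01	6	4	5	6	4	5	6	4	5	6	4	5	6	4	5
G02	4	5	6	4	5	6	4	5	6	4	5	6	4	5	6
G03	5	6	4	5	6	4	5	6	4	NA	6	4	5	6	4
G04	5	5	5	5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5	0.5
G05	4	5	6	4	5	6	4	5	6	4	5	6	4	5	6
G06	2	2	2	2	2	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8	0.8
G07	2	2	2	2	1	1	1	1	1	1	1	1	1	1	1
G08	4	5	6	4	5	6	4	5	6	4	5	6	4	5	6
G09	5	6	4	5	6	4	5	6	4	5	6	4	5	6	4
G10	6	4	5	6	4	5	6	4	5	6	4	5	6	4	5
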