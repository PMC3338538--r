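subject	faces	buildings	animals
S1	69	30	57
S2	52	43	76
S3	76	11	51
S4	47	58	50
S5	63	50	54
S6	74	42	72
S7	65	43	57
S8	70	36	63
S9	43	31	33
S10	67	44	64
S11	18	32	33
S12	37	20	24
S13	69	31	68
S14	51	22	41
S15	55	58	56
S16	77	53	68
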