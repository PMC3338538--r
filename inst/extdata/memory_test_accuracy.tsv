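subject	faces	buildings	animals
S1	48.9	35.6	46.7
S2	55.6	11.1	28.9
S3	55.6	42.2	64.4
S4	75.6	53.3	68.9
S5	68.9	51.1	73.3
S6	62.2	31.1	46.7
S7	77.8	55.6	75.6
S8	77.8	42.2	68.9
S9	71.1	57.8	71.1
S10	51.1	22.2	51.1
S11	55.6	42.2	64.4
S12	53.3	8.9	35.6
S13	55.6	42.2	57.8
S14	40.0	15.6	48.9
S15	62.2	42.2	51.1
S16	64.4	42.2	46.7
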