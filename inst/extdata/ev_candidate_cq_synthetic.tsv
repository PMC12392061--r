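assay	PSC_EV_C1	PSC_EV_C2	PSC_EV_C3	PSC_IN_C1	PSC_IN_C2	PSC_IN_C3	NSC_EV_C1	NSC_EV_C2	NSC_EV_C3	NSC_IN_C1	NSC_IN_C2	NSC_IN_C3	FPP_EV_C1	FPP_EV_C2	FPP_EV_C3	FPP_IN_C1	FPP_IN_C2	FPP_IN_C3
hsa-miR-622	24.3	24.3	24.3	33.4	33.4	33.4	36.0	36.0	36.0	36.0	36.0	36.0	36.0	36.0	36.0	36.0	36.0	36.0
hsa-miR-639	26.8	26.8	26.8	31.9	31.9	31.9	26.9	26.9	26.9	30.35	30.2	30.05	27.7	27.7	27.7	30.7	30.7	30.7
hsa-miR-1300	25.0	25.0	25.0	29.9	32.45	32.45	25.2	25.2	25.2	31.9	31.9	31.9	26.2	26.2	26.2	31.0	31.0	31.0
hsa-miR-663b	23.1	23.1	23.1	28.0	35.5	35.5	24.7	24.7	24.7	37.0	37.0	37.0	26.4	26.4	26.4	36.9	36.9	36.9
hsa-miR-1290	30.3	30.3	30.3	29.6	29.6	29.6	27.3	27.3	27.3	29.5	35.65	35.65	26.7	26.7	26.7	30.7	30.7	30.7
ctrl-ubiq-1	19.0	19.2	18.8	19.1	19.0	18.9	19.3	19.0	19.1	18.8	19.2	19.0	19.1	18.9	19.0	19.2	19.1	18.8
ctrl-ubiq-2	21.0	20.8	21.2	20.9	21.1	21.0	20.7	21.0	21.3	21.1	20.9	21.0	21.2	20.8	21.0	20.9	21.1	21.0
ctrl-ubiq-3	23.5	23.4	23.6	23.5	23.3	23.7	23.6	23.5	23.4	23.5	23.6	23.4	23.3	23.5	23.7	23.4	23.6	23.5
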