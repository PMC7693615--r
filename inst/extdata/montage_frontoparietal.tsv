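channel	source	detector	label	hemisphere	roi	distance
1	S1	D2	CH1	left	DLPFC	0.03
2	S1	D1	CH2	left	DLPFC	0.03
3	S2	D3	CH3	left	DLPFC	0.03
4	S2	D2	CH4	left	DLPFC	0.03
5	S2	D3	CH5	left	VLPFC	0.03
6	S3	D3	CH6	left	VLPFC	0.03
7	S3	D4	CH7	left	VLPFC	0.03
8	S4	D4	CH8	left	VLPFC	0.03
9	S4	D5	CH9	left	VLPFC	0.03
10	S4	D4	CH10	right	VLPFC	0.03
11	S5	D6	CH11	right	VLPFC	0.03
12	S5	D5	CH12	right	VLPFC	0.03
13	S6	D7	CH13	right	VLPFC	0.03
14	S6	D6	CH14	right	DLPFC	0.03
15	S6	D7	CH15	right	DLPFC	0.03
16	S7	D7	CH16	right	VLPFC	0.03
17	S7	D8	CH17	right	DLPFC	0.03
18	S8	D8	CH18	right	DLPFC	0.03
19	S8	D9	CH19	left	IPL	0.03
20	S8	D8	CH20	left	SPL	0.03
21	S9	D10	CH21	left	IPL	0.03
22	S9	D9	CH22	left	IPL	0.03
23	S10	D11	CH23	left	IPL	0.03
24	S10	D10	CH24	left	SPL	0.03
25	S10	D11	CH25	left	IPL	0.03
26	S11	D12	CH26	left	excluded	0.03
27	S12	D11	CH27	left	excluded	0.03
28	S12	D12	CH28	left	excluded	0.03
29	S12	D13	CH29	right	IPL	0.03
30	S12	D12	CH30	right	SPL	0.03
31	S13	D14	CH31	right	IPL	0.03
32	S13	D13	CH32	right	IPL	0.03
33	S14	D15	CH33	right	IPL	0.03
34	S14	D14	CH34	right	SPL	0.03
35	S14	D15	CH35	right	IPL	0.03
36	S15	D16	CH36	right	excluded	0.03
37	S16	D15	CH37	right	excluded	0.03
38	S16	D16	CH38	right	excluded	0.03
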