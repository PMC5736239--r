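1	121236957	123476957
2	91689898	94689898
3	90587544	93487544
4	49354874	52354874
5	46441398	49441398
6	58938125	61938125
7	58058273	61058273
8	43958052	46958052
9	46367184	49367184
10	39244941	41624941
11	51450781	54450781
12	34747961	36142961
13	16000000	17868000
14	15070000	18070000
15	15260000	18260000
16	35143302	36943302
17	22187133	22287133
18	15400898	16764896
19	26923622	29923622
20	26267569	28033230
21	10260000	13260000
22	11330000	14330000
X	58598737	61598737
Y	11253954	12308578
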