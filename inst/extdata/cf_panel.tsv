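gene	chrom	start	end	declared_n_cpg	declared_size
ATF1	chr12	50764850	50765098	12	249
CFTR	chr7	117479627	117479759	10	133
DUOX2	chr15	45114541	45114722	11	182
EDNRA	chr4	147480957	147481216	21	260
SCNN1G	chr16	23182420	23182665	23	246
GSTM1	chr1	109687687	109687897	13	211
GSTM3	chr1	109740573	109740793	9	221
HMOX1	chr22	35381269	35381436	5	168
IFRD1	chr7	112450883	112451040	12	158
MUC5AC	chr11	1194622	1194807	13	186
TGFB1	chr19	41353542	41353740	19	199
TLR2	chr4	153684576	153684704	12	129
TLR5	chr1	223142813	223142967	8	155
YY1	chr14	100240497	100240751	26	255
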