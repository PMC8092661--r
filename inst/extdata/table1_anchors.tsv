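# Anchor table tying the generic alignment numbering to native (author)
# residue numbers for the receptors with published structures.
# Columns are 1-based; native numbering is author numbering, verbatim.
# Within a block, native number differences equal alignment differences.
taxon	block	block_aln_start	block_aln_end	aln_pos	native	aa
hRXRa	H4-H5	105	115	109	305	W
hRXRa	H4-H5	105	115	111	307	E
hRXRa	H7	198	218	202	348	R
hRXRa	H7	198	218	206	352	E
hRXRa	H7	198	218	207	353	L
hRXRa	H7	198	218	210	356	K
hRXRa	H7	198	218	214	360	M
hRXRa	H8	219	226	220	366	E
hRXRa	loopH8-H9	258	266	262	379	D
hRXRa	loopH8-H9	258	266	263	380	S
hRXRa	H10	305	318	309	414	R
hRXRa	H10	305	318	316	421	R
hRXRa	H11	319	330	321	426	R
hRXRa	H11	319	330	322	427	S
hRXRa	H11	319	330	326	431	K
hHNF4a	H4-H5	105	115	109	224	A
hHNF4a	H4-H5	105	115	111	226	E
hHNF4a	H7	198	218	202	267	R
hHNF4a	H7	198	218	206	271	E
hHNF4a	H7	198	218	207	272	L
hHNF4a	H7	198	218	210	275	P
hHNF4a	H7	198	218	214	279	L
hHNF4a	H8	219	226	220	285	E
hHNF4a	loopH8-H9	258	266	262	298	D
hHNF4a	loopH8-H9	258	266	263	299	A
hHNF4a	H10	305	318	309	333	R
hHNF4a	H10	305	318	316	340	L
hHNF4a	H11	319	330	321	345	Q
hHNF4a	H11	319	330	322	346	S
hHNF4a	H11	319	330	326	350	Q
hCOUP-TFII	H4-H5	105	115	109	249	W
hCOUP-TFII	H4-H5	105	115	111	251	E
hCOUP-TFII	H7	198	218	202	293	R
hCOUP-TFII	H7	198	218	206	297	E
hCOUP-TFII	H7	198	218	207	298	Q
hCOUP-TFII	H7	198	218	210	301	K
hCOUP-TFII	H7	198	218	214	305	L
hCOUP-TFII	H8	219	226	220	311	E
hCOUP-TFII	loopH8-H9	258	266	262	324	D
hCOUP-TFII	loopH8-H9	258	266	263	325	A
hCOUP-TFII	H10	305	318	309	359	R
hCOUP-TFII	H10	305	318	316	366	R
hCOUP-TFII	H11	319	330	321	371	R
hCOUP-TFII	H11	319	330	322	372	T
hCOUP-TFII	H11	319	330	326	376	S
hPNR	H4-H5	105	115	109	257	W
hPNR	H4-H5	105	115	111	259	E
hPNR	H7	198	218	202	301	R
hPNR	H7	198	218	206	305	E
hPNR	H7	198	218	207	306	T
hPNR	H7	198	218	210	309	R
hPNR	H7	198	218	214	313	L
hPNR	H8	219	226	220	319	E
hPNR	loopH8-H9	258	266	262	332	E
hPNR	loopH8-H9	258	266	263	333	T
hPNR	H10	305	318	309	367	R
hPNR	H10	305	318	316	374	L
hPNR	H11	319	330	321	379	R
hPNR	H11	319	330	322	380	F
hPNR	H11	319	330	326	384	E
hRARa	H4-H5	105	115	109	265	C
hRARa	H4-H5	105	115	111	267	D
hRARa	H7	198	218	202	307	D
hRARa	H7	198	218	206	311	A
hRARa	H7	198	218	207	312	F
hRARa	H7	198	218	210	315	Q
hRARa	H7	198	218	214	319	L
hRARa	H8	219	226	220	325	E
hRARa	loopH8-H9	258	266	262	338	D
hRARa	loopH8-H9	258	266	263	339	R
hRARa	H10	305	318	309	373	M
hRARa	H10	305	318	316	380	K
hRARa	H11	319	330	321	385	R
hRARa	H11	319	330	322	386	S
hRARa	H11	319	330	326	390	K
hTRa	H4-H5	105	115	109	309	C
hTRa	H4-H5	105	115	111	311	E
hTRa	H7	198	218	202	351	D
hTRa	H7	198	218	206	355	D
hTRa	H7	198	218	207	356	L
hTRa	H7	198	218	210	359	S
hTRa	H7	198	218	214	363	F
hTRa	H8	219	226	220	369	E
hTRa	loopH8-H9	258	266	262	382	D
hTRa	loopH8-H9	258	266	263	383	R
hTRa	H10	305	318	309	417	F
hTRa	H10	305	318	316	424	K
hTRa	H11	319	330	321	429	R
hTRa	H11	319	330	322	430	M
hTRa	H11	319	330	326	434	C
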