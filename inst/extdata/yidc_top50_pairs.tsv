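aa_i	res_i	region_i	aa_j	res_j	region_j	d_model	d_ref	status_printed
TRP	354	TM2						indel
GLY	355	TM2						indel
PHE	356	TM2						indel
PHE	356	TM2	ARG	533	c-term			topology_violation
ILE	358	TM2	GLY	512	Loop5-6	9.1	6.1	
ILE	359	TM2	VAL	519	TM6	6.5	5.2	
ILE	359	TM2	LEU	515	TM6	8.5	7.9	
ILE	359	TM2						indel
ILE	361	TM2	LEU	436	TM3	7.9	8.2	
THR	362	TM2	PRO	371	TM2			intrahelical
PHE	363	TM2	VAL	523	TM6	5.2	6.1	
GLY	367	TM2	VAL	523	TM6	6.0	8.2	
MET	369	TM2	ILE	432	TM3	9.9	8.4	
LEU	372	Loop2-3	PRO	510	Loop5-6			topology_violation
SER	379	Loop2-3	PRO	425	TM3	10.2	9.9	
LEU	386	Loop2-3	VAL	417	Loop2-3	7.5	7.1	
LEU	386	Loop2-3	LEU	411	Loop2-3	6.2	6.1	
PRO	388	Loop2-3	GLN	429	TM3			topology_violation
LYS	389	Loop2-3	ALA	414	Loop2-3	10.5	9.8	
LYS	389	Loop2-3	GLU	415	Loop2-3	11.2	10.0	
ILE	390	Loop2-3	MET	408	Loop2-3	6.8	6.2	
MET	393	Loop2-3	ILE	404	Loop2-3	7.9	7.4	
MET	393	Loop2-3	LEU	411	Loop2-3	8.2	7.7	
ARG	394	Loop2-3	ILE	404	Loop2-3	8.5	8.1	
ARG	396	Loop2-3	GLU	407	Loop2-3	8.9	8.4	
CYS	423	TM3	GLN	528	TM6	16.2	20.9	
PRO	425	TM3	PRO	499	TM5	10.2	20.5	
PHE	433	TM3	THR	524	TM6	11.0	14.9	
LEU	436	TM3	GLY	512	Loop5-6	7.6	8.3	
TYR	437	TM3	LEU	513	Loop5-6	9.8	6.4	
TRP	454	Loop3-4	ASP	462	Loop3-4	6.6	7.0	
TRP	454	Loop3-4	PRO	468	TM4	16.0	11.5	
TRP	454	Loop3-4	SER	511	Loop5-6	9.8	8.3	
ILE	455	Loop3-4	LEU	467	TM4	9.8	10.1	
ILE	455	Loop3-4	ILE	466	TM4	11.0	8.0	
ASP	462	Loop3-4	PRO	468	TM4	12.5	6.8	
ASP	462	Loop3-4	SER	511	Loop5-6	11.1	4.2	
TYR	465	TM4	LEU	507	TM5	10.4	8.7	
LEU	467	TM4	LEU	515	TM6	11.6	6.6	
PRO	468	TM4	LEU	513	TM6	14.5	8.8	
LEU	470	TM4	ILE	518	TM6	6.3	5.4	
MET	471	TM4	PHE	502	TM5	8.8	4.9	
GLY	472	TM4	THR	503	TM5	6.7	5.3	
GLY	472	TM4	GLN	479	TM4			intrahelical
THR	474	TM4	ASN	521	TM6	4.7	3.7	
THR	474	TM4	ILE	525	TM6	6.7	7.8	
ILE	478	TM4	ILE	525	TM6	9.0	5.0	
THR	485	Loop4-5						indel
PHE	506	TM5	VAL	514	TM6	14.4	4.2	
GLY	512	Loop5-6	GLN	532	TM6			topology_violation
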