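patient_id	birth_year	sex	type	chr	band	start	end	class	origin
CNV1	2019	F	dup	16	p13.3	50,000	6,249,999	P	de_novo
CNV2	2018	M	dup	6	q25.1-q27	151,478,865	170,590,912	LP	paternal
CNV3	2018	M	del	6	q12-q14.1	67,390,107	76,290,283	LP	de_novo
CNV3	2018	M	del	15	q21.1-q21.3	48,907,803	54,907,802	LP	de_novo
CNV4	2007	F	del	7	q11.23	73,285,998	74,585,671	P	de_novo
CNV5	2017	M	del	5	q14.2-q14.3	82,604,181	90,004,183	unknown	de_novo
CNV6	2018	M	del	14	q32.2	98,433,663	100,733,663	P	de_novo
CNV7	2016	M	del	7	q11.23	73,285,998	74,585,671	P	de_novo
CNV8	2017	M	del	9	q31.1-q31.3	101,537,718	111,737,720	P	uncertain
CNV9	2015	F	dup	10	p15.3-p14	54,060	6,758,038	P	uncertain
CNV9	2015	F	del	18	q22.3-q23	73,332,765	80,219,365	P	uncertain
CNV10	2021	M	dup	2	q36.3-q37.3	227,035,284	242,057,849	LP	uncertain
CNV10	2021	M	del	4	q35.2	187,378,846	189,878,845	VUS	uncertain
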