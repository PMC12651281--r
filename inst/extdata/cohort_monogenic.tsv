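patient_id	birth_year	sex	gene	diagnosis	onset	perinatal	vision	neuro	seizure	eeg	mri	mental	motor	id	dysmorph	skeletal	anomalies	family	syndrome
ID1.1	2014	F	NKX6-2	Cerebral palsy	4		3	4					4	4			2	2	
ID1.2	2009	M	NKX6-2	Cerebral palsy			3	4					4	4			2	2	
ID2.1	2019	M	NKX6-2	Cerebral palsy	3		3	4	3	3	3		4	4			2	2	
ID2.2	2013	M	NKX6-2	Cerebral palsy	3		3	4	3	3	3		4	4			2	2	
ID2.3	2011	F	NKX6-2	Cerebral palsy	3		3	4	3	3	3		4	4			2	2	
ID3	2019	F	TCF4	Developmental delay	3	3					2	4	3	4					4
ID4	2016	F	TCF4	Developmental delay	2	3						4	2	4	3				4
ID5	2014	F	SCN2A	Epilepsy and developmental delay	4				4				4	4					
ID6.1	2010	M	SCN2A	ID, ASD	1							3	2	2				2	
ID6.2	2014	M	SCN2A	ID, ASD								3	2	2				2	
ID7	2013	F	PAH	ID, ASD	3						3	3	2	3					
ID8	2015	M	PAH	ID, ASD	2							3	2	3					
ID9	2018	M	IQSEC2	Developmental delay, epilepsy	3				3	3	2		3	4					
ID10	2018	F	KCNMA1	Epilepsy and developmental delay	2				2	3			2	2					
ID11	2002	M	POLR1C	leukodystrophy	1		4				4	3	2	2					
ID12.1	2010	M	GNPAT	Developmental delay, cataracts, chondrodysplasia	4								4	4		4		2	
ID12.2	2014	M	GNPAT	Developmental delay, cataracts, chondrodysplasia	4								4	4		4		2	
ID13.1	2020	M	PGAP3	Intelectual disability, autism								3		3				2	
ID13.2	2014	F	PGAP3	Intelectual disability, autism								3		3				2	
ID14	2019	M	HNRNPU	Developmental delay, epilepsy	3				2	3	4	3	2	2				2	
ID15.1	2015	M	PLP1	Cerebral palsy/Spastic paraplegia	3	4	3	3			3		4	4		4		2	
ID15.2	2018	M	PLP1	Cerebral palsy/Spastic paraplegia	3		3	3			3		4	4		4		3	
ID16	2016	M	ADSL	Developmental delay	2				2	3	4		3	4				2	
ID17	2015	M	ACTG1	ID, Dandy Walker syndrome	3	4						4		3	3				4
ID18	2019	F	ATP1A3	Cerebral palsy	3	4		2	3		4		4	4	3				
ID18.1	2019	F	CHD3	Cerebral palsy															4
ID19	2018	F	NIPBL	ID, ASD	4								2	4			3		4
ID20	2020	M	NGLY1	Intellectual disability	3						4		4	4					
ID21	2018	M	SMAD6	Cerebral palsy	2	4		2						2					
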