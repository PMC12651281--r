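gene	pathway_category
POLR1C	transcription_rna_processing
TCF4	transcription_rna_processing
HNRNPU	transcription_rna_processing
NIPBL	transcription_rna_processing
ACTG1	transcription_rna_processing
CHD3	transcription_rna_processing
SCN2A	ion_channel_metabolic
PAH	ion_channel_metabolic
IQSEC2	ion_channel_metabolic
GNPAT	ion_channel_metabolic
KCNMA1	ion_channel_metabolic
ADSL	ion_channel_metabolic
NGLY1	ion_channel_metabolic
NKX6-2	myelination_structural_signaling
PLP1	myelination_structural_signaling
PGAP3	myelination_structural_signaling
SMAD6	myelination_structural_signaling
ATP1A3	myelination_structural_signaling
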