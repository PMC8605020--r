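family	reference_id	position	allowed_residues
merB	merB_ref	96	C
merB	merB_ref	99	D
merB	merB_ref	117	C
merB	merB_ref	159	C
merA	merA_ref	136	C
merA	merA_ref	141	C
merA	merA_ref	558	C
merA	merA_ref	559	C
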