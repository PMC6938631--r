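instance_id	class_id	source_ref	readout_type	has_wildtype_control	has_null_control	has_technical_replicates	has_biological_replicates	basis
pooled	enzymatic_activity	synthetic	quantitative	TRUE	TRUE	TRUE	TRUE	documented
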