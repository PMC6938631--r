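variant_id	readout_value
VUS1	75
VUS2	45
VUS3	12
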