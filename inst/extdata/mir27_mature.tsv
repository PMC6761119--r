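name	sequence	mirbase_id
hsa-miR-27a-3p	uucacaguggcuaaguuccgc	MIMAT0000084
hsa-miR-27b-3p	uucacaguggcuaaguucugc	MIMAT0000419
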