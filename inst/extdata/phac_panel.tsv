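pair_id	class	fwd	rev	expected_bp	ta_c
phaCF1/phaCR1	I	ATCAAYAAGTAYTACATYCTT	TCCAGWASARCAKRTC	558	44
phaCF3/phaCR3	II	CTGGATGCGCCCCAACGATC	SAYCGGCGTRCCRCACA	203	58
phaCF5/phaCR5	III	GAHCATATTTCTAGCACAGACC	CCARTCNADCABRTAC	708	46
phaCF8/phaCR8	III/IV	GTGTAYNTGYTDGAYTGGGG	GGRATRTTKCCVARYGTATC	352	50
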