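mouse_name	human_name	mouse_seq	human_seq	seed_mouse	seed_human	seed_match	note
mmu-miR-92b-3p	hsa-miR-92b-3p	UAUUGCACUCGUCCCGGCCUCC	UAUUGCACUCGUCCCGGCCUCC	AUUGCAC	AUUGCAC	TRUE	Identical
mmu-miR-133a-3p	hsa-miR-133a-3p	UUUGGUCCCCUUCAACCAGCUG	UUUGGUCCCCUUCAACCAGCUG	UUGGUCC	UUGGUCC	TRUE	Identical
mmu-miR-326-5p	hsa-miR-326	GGGGGCAGGGCCUUUGUGAAGGCG	CCUCUGGGCCCUUCCUCCAG	GGGGCAG	CUCUGGG	FALSE	Not identical
mmu-miR-125b-5p	hsa-miR-125b-5p	UCCCUGAGACCCUAACUUGUGA	UCCCUGAGACCCUAACUUGUGA	CCCUGAG	CCCUGAG	TRUE	Identical
mmu-miR-148a-3p	hsa-miR-148a-3p	UCAGUGCACUACAGAACUUUGU	UCAGUGCACUACAGAACUUUGU	CAGUGCA	CAGUGCA	TRUE	Identical
mmu-miR-30b-5p	hsa-miR-30b-5p	UGUAAACAUCCUACACUCAGCU	UGUAAACAUCCUACACUCAGCU	GUAAACA	GUAAACA	TRUE	Identical
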