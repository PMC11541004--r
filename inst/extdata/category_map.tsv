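profile_id	category
hmm_anti_crispr	anti_crispr
hmm_anti_restriction	anti_restriction
hmm_sos_inhibitor	sos_inhibitor
hmm_mtase	mtase
hmm_ssb	ssb
hmm_toxin_antitoxin	toxin_antitoxin
hmm_mobility	mobility
hmm_transposase	transposase
hmm_umu_like	umu_like
hmm_relaxase	relaxase
hmm_traM	traM
hmm_other	other
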