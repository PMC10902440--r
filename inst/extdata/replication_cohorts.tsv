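group	study	or	ci_low	ci_high	model
x11538_outcome_replication	FinnGen PsA	0.44	0.25	0.78	fixed
x11538_outcome_replication	IMID Consortium PsA	0.01	0.01	0.72	fixed
rikenellaceae_outcome_replication	FinnGen PsA	0.62	0.44	0.88	fixed
rikenellaceae_outcome_replication	IMID Consortium PsA	0.37	0.14	0.93	fixed
x11538_exposure_replication	TwinsUK-KORA	0.44	0.25	0.78	fixed
x11538_exposure_replication	CLSA	0.68	0.55	0.86	fixed
rikenellaceae_exposure_replication	MiBioGen	0.62	0.44	0.88	fixed
rikenellaceae_exposure_replication	Dutch Microbiome Project	0.58	0.35	0.96	fixed
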