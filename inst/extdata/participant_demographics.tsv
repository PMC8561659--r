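study	treatment	avg_age	sd_age	n_females	n_males	samples_per_participant	total_samples
daily_dynamics	none	36.9	18.5	5	5	9	90
acute_perturbation	water	26.9	5.1	3	4	3	21
acute_perturbation	antiseptic	27.9	4.3	3	4	3	21
acute_perturbation	alcohol_free	32	5.2	3	4	3	21
acute_perturbation	soda	30.1	3.9	2	5	3	21
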