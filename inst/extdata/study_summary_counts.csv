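key,value
all_reports,420114
pediatric_reports,60433
included_reports,15857
events,20681
n_male,9740
n_female,6103
n_sex_unknown,14
n_age_unknown,6
n_serious,1052
n_non_serious,14805
n_new_serious,154
n_new_non_serious,1573
n_injection,15271
n_oral,581
adr_total_printed,23377
n_distinct_terms,153
n_soc,21
signals_ror,211
signals_prr,207
signals_mhra,376
signals_consensus,206
signals_off_label,73
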