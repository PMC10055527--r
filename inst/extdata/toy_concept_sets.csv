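"set_name","role","concept_id"
"pregnancy_loss","pregnancy_loss","OMOP_LOSS"
"rpl_diagnosis","rpl_diagnosis","OMOP_RPL_DX"
"history_of_loss","history_of_loss","OMOP_HX_LOSS"
"live_birth","live_birth","OMOP_LIVEBIRTH"
"control_exclusion","control_exclusion","OMOP_PRETERM_BIRTH"
"control_exclusion","control_exclusion","OMOP_ECTOPIC"
"incident_pregnancy","incident_pregnancy","OMOP_LOSS"
"incident_pregnancy","incident_pregnancy","OMOP_LIVEBIRTH"
"incident_pregnancy","incident_pregnancy","OMOP_RPL_DX"
"gender_diverse","gender_diverse","OMOP_GENDER_DIVERSE"
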