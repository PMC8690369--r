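table	column	type	notes
patients	patient_id	character	unique patient identifier
patients	sex	character	"F" or "M"
patients	birth_date	date	ISO-8601, day precision
patients	death_date	date	ISO-8601; empty if alive at extraction
hospitalisations	patient_id	character
hospitalisations	admission_date	date	admission <= discharge
hospitalisations	discharge_date	date
hospitalisations	diagnosis_code	character	one code per row; repeats allowed
hospitalisations	code_system	character	"ICD10" or "ICD9"
outpatient_visits	patient_id	character
outpatient_visits	visit_date	date
outpatient_visits	diagnosis_code	character
outpatient_visits	code_system	character	"ICD10" or "ICD9"
dispensations	patient_id	character
dispensations	dispense_date	date
dispensations	atc_code	character	full-precision ATC code
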