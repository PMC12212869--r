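column	type	required	description
id	string	no	opaque record identifier; generated if absent
ga_days	integer or "W+D"	yes	gestational age at birth in days (or obstetric notation, e.g. 38+4); cohort window 168-300 days (24+0 to 42+6)
sex	male|female	yes	infant sex; missing or unknown values are excluded from validation cohorts
birthweight_g	number	yes	birthweight in grams; values outside 100-7000 g are excluded as implausible (configurable)
stillbirth	logical	no	death of the infant prior to birth
neonatal_death	logical	no	death within 28 days of a livebirth; forced FALSE when stillbirth is TRUE
nicu	logical	no	admission to the neonatal intensive care unit
apgar5	integer 0-10	no	Apgar score at 5 minutes; derived outcomes apgar5_lt7 / apgar5_lt4 use this column
delivery_mode	enum	no	unassisted_vaginal | instrumental | elective_cs | emergency_cs
induced_for_poor_growth	logical	no	delivery timed for suspected poor fetal growth
operative_for_fetal_distress	logical	no	instrumental birth or cesarean for fetal distress
multiple_pregnancy	logical	no	exclusion flag: non-singleton pregnancy
congenital_anomaly	logical	no	exclusion flag: congenital anomaly of any type
true_fgr	logical	no	synthetic cohorts only: latent growth-restriction label
true_z	number	no	synthetic cohorts only: latent weight z-score
true_preterm	logical	no	synthetic cohorts only: drawn from the preterm tail (< 259 days)
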