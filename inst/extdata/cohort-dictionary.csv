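column,type,units,required,description
patient_id,string,,yes,Opaque patient identifier
baseline_dflc,numeric,mg/dL,yes,Difference of involved minus uninvolved serum free light chains at diagnosis
landmark_dflc,numeric,mg/dL,yes,dFLC at the response landmark
landmark_ifix_negative,logical,,yes,Serum AND urine immunofixation negative at the landmark
landmark_flc_ratio_normal,logical,,yes,Free light-chain ratio normal at the landmark
baseline_ntprobnp,numeric,pg/mL,yes,NT-proBNP at diagnosis
landmark_ntprobnp,numeric,pg/mL,yes,NT-proBNP at the landmark
baseline_proteinuria,numeric,mg/24h,yes,24-hour urine protein at diagnosis
landmark_proteinuria,numeric,mg/24h,yes,24-hour urine protein at the landmark
baseline_egfr,numeric,mL/min/1.73m2,yes,Estimated glomerular filtration rate at diagnosis
landmark_egfr,numeric,mL/min/1.73m2,yes,eGFR at the landmark
baseline_alp,numeric,U/L,yes,Alkaline phosphatase at diagnosis
landmark_alp,numeric,U/L,yes,Alkaline phosphatase at the landmark
heart_involved,logical,,yes,Cardiac amyloid involvement
kidney_involved,logical,,yes,Renal amyloid involvement
liver_involved,logical,,yes,Hepatic amyloid involvement
on_dialysis_at_baseline,logical,,yes,On dialysis at diagnosis (excluded from renal response assessment)
os_time,numeric,months,yes,Follow-up from treatment start to death or censoring
os_event,logical,,yes,Death observed
dialysis_time,numeric,months,no,Follow-up from treatment start to dialysis initiation or censoring
dialysis_event,logical,,no,Dialysis initiation observed
landmark_months,numeric,months,yes,Actual response-assessment time (nominal 6 or 12; +/- 2 accepted)
age,numeric,years,no,Age at diagnosis
sex_male,logical,,no,Male sex
baseline_ifix_negative,logical,,no,Immunofixation negative at diagnosis
baseline_flc_ratio_normal,logical,,no,FLC ratio normal at diagnosis
baseline_troponin_t,numeric,ng/mL,no,Troponin-T at diagnosis (staging only)
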