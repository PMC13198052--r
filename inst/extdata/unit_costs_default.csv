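# Illustrative societal unit-cost table (EUR, 2019/2020 price level style).
# Schema: item,unit,eur. The frailty screening tariff and the statutory
# co-payment constants are fixed study quantities; all other values are
# illustrative defaults for simulation and testing.
item,unit,eur
hospital_inpatient,day,700
hospital_outpatient,visit,120
psychiatry,day,450
physician_visits,visit,45
therapist_visits,visit,40
mobile_nursing,hour,45
informal_care,hour,30
household_assistance,hour,25
neighbour_help,hour,25
day_care,day,80
short_term_care,day,110
nursing_home,day,120
rehabilitation,day,250
auxiliary_aids,item,60
session_mobile,session,28
session_outpatient,session,21
session_outpatient_transport,session,46
session_part_inpatient,session,65
session_inpatient,session,310
frailty_screening,screening,26
sdm_conference,conference,309
investment_per_case,case,800
copay_rate_per_day,day,10
copay_cap_days,days,28
copay_exempt_share,share,0.5
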