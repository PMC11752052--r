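variable,group,k,mean,sd
n_sessions,active,68,12.94,11.02
n_sessions,control,41,5.71,6.10
sessions_per_week,active,62,1.28,0.71
sessions_per_week,control,37,0.58,0.67
session_minutes,active,57,65.52,31.63
session_minutes,control,36,29.12,35.01
total_hours,active,59,13.80,9.88
total_hours,control,37,5.17,7.63
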