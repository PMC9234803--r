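"line_id","strain","evolved","day","gene","mutation","identified"
"mutS_01","mutS",TRUE,,"ntrB","A289C",TRUE
"mutS_02","mutS",TRUE,,"ntrB","A289C",TRUE
"mutS_03","mutS",TRUE,,"ntrB","A289C",TRUE
"mutS_04","mutS",TRUE,,"ntrB","A289C",TRUE
"mutS_05","mutS",TRUE,,"ntrB","A289C",TRUE
"mutS_06","mutS",TRUE,,"ntrB","A289C",TRUE
"mutS_07","mutS",TRUE,,"ntrB","A289C",TRUE
"mutS_08","mutS",TRUE,,"ntrB","T323C",TRUE
"mutS_09","mutS",TRUE,,"ntrB","T407C",TRUE
"mutS_10","mutS",TRUE,,"ntrB","A608G",TRUE
"mutS_11","mutS",TRUE,,"ntrB","A608G",TRUE
"mutS_12","mutS",TRUE,,"ntrB","A683G",TRUE
"mutS_13","mutS",TRUE,,"glnK","T11C",TRUE
"mutS_14","mutS",TRUE,,"glnK","A131G",TRUE
"mutS_15","mutS",TRUE,,"glnK","A263G",TRUE
"mutS_16","mutS",TRUE,,"unidentified","",FALSE
"mutS_17","mutS",TRUE,,"unidentified","",FALSE
"mutS_18","mutS",TRUE,,"unidentified","",FALSE
"mutS_19","mutS",TRUE,,"unidentified","",FALSE
"mutS_20","mutS",TRUE,,"unidentified","",FALSE
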