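"line_id","strain","evolved","day","gene","mutation","identified"
"AR2_01","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_02","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_03","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_04","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_05","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_06","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_07","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_08","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_09","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_10","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_11","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_12","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_13","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_14","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_15","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_16","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_17","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_18","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_19","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_20","AR2",TRUE,,"ntrB","A289C",TRUE
"AR2_21","AR2",TRUE,,"ntrB","T326C",TRUE
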