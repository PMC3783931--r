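"id","nihss_acute","nihss_24h","sbp","dbp","inr","anticoagulant","hemorrhage","onset_to_treatment","treated"
"SYN-0001",19,14,175.297635328025,79.279247346567,1.0942340541631,FALSE,FALSE,1.98844368220307,TRUE
"SYN-0002",14,7,162.494438404683,87.8529541217722,1.05393251143396,FALSE,FALSE,2.54100615053903,TRUE
"SYN-0003",10,4,139.490605490282,80.3955116181169,1.12208875948563,FALSE,FALSE,1.32835128856823,TRUE
"SYN-0004",13,7,115.425995402038,88.5920457111206,1.04854781311005,FALSE,FALSE,2.25981079405174,TRUE
"SYN-0005",11,6,133.321955983993,66.1962351982947,1.15957396430895,FALSE,FALSE,2.22447760829236,TRUE
"SYN-0006",4,4,112.174148575868,68.2327791606076,1.28654954386875,TRUE,FALSE,3.28990253817756,FALSE
"SYN-0007",6,5,139.304662381765,79.0767928271089,0.999200143199414,TRUE,FALSE,1.36127749131992,FALSE
"SYN-0008",4,2,165.52214598516,85.5454234289937,1.25766432099044,FALSE,FALSE,3.60231329104863,FALSE
"SYN-0009",3,0,161.682760205586,116.39464039891,1.16136301672086,FALSE,FALSE,1.46291036831681,FALSE
"SYN-0010",7,8,146.053821532987,103.671652005287,0.920138472598046,TRUE,FALSE,3.32866078903899,TRUE
"SYN-0011",3,0,143.902367358096,87.9082578979433,1.25104095404968,FALSE,FALSE,1.35885469026398,TRUE
"SYN-0012",7,9,166.916780832689,73.8774284895044,1.03839738583192,FALSE,FALSE,3.15776586539578,TRUE
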