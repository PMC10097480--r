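"recording_id","rater_1","rater_2","rater_3"
"R01",1,1,1
"R02",1,1,1
"R03",1,1,1
"R04",1,1,1
"R05",1,1,1
"R06",1,1,1
"R07",1,1,1
"R08",1,1,1
"R09",1,1,1
"R10",1,1,1
"R11",1,1,1
"R12",1,1,1
"R13",1,1,1
"R14",1,1,1
"R15",1,1,1
"R16",1,1,1
"R17",1,1,1
"R18",1,1,1
"R19",1,1,1
"R20",1,1,1
"R21",1,1,0
"R22",1,0,0
"R23",1,0,0
"R24",1,0,0
"R25",1,0,0
"R26",1,0,0
"R27",1,0,0
"R28",1,0,0
"R29",0,0,0
"R30",0,0,0
"R31",0,0,0
"R32",0,0,0
"R33",0,0,0
"R34",0,0,0
"R35",0,0,0
"R36",0,0,0
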