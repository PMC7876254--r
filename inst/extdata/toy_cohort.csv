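"participant_id","age_years","group","asd_label"
"s001",15.9776725219563,"ASD",1
"s002",16.2449049595743,"TD",0
"s003",8.43367441743612,"TD",0
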