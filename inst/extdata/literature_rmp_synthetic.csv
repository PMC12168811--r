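study_id,species,stimulus,duration_h,rmp_ctrl_mV,rmp_infl_mV,reported_change_rmp
synth01,rat,inflammatory soup,0.1,-57.0,-46.5,increase
synth02,mouse,PGE2,24,-60.2,-59.8,no_change
synth03,rat,bradykinin,0.2,-62.1,-51.3,increase
synth04,mouse,TNF,24,-55.4,-52.0,increase
synth05,rat,NGF,72,-58.9,-58.1,no_change
synth06,mouse,conditioned medium,24,-61.5,-49.0,increase
synth07,rat,serotonin,0.1,-56.8,-53.2,increase
synth08,human iPSC,inflammatory soup,24,-63.0,-62.6,no_change
synth09,mouse,LPS,24,-59.7,-55.9,increase
synth10,rat,PGE2,0.2,-60.0,-48.7,increase
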