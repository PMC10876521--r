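sample_id,group,experiment
lab_1,labeled,1
lab_2,labeled,1
lab_3,labeled,1
ctl_1,control,1
ctl_2,control,1
ctl_3,control,1
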