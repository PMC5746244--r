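intervention,annual_volume,volume_cv
colonoscopy,10,0.2
depression,500,0.2
cholesterol,50,0.2
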