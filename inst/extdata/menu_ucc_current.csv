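intervention,annual_volume,volume_cv
obesity,500,0.2
hypertension,500,0.2
tobacco,500,0.2
alcohol,500,0.2
condoms,500,0.2
hiv,500,0.2
syphilis,500,0.2
influenza_50plus,5,0.2
influenza_15_49,50,0.2
diabetes,100,0.2
mammography,10,0.2
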