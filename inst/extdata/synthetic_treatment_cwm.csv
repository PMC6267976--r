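unit_id,seed_mass,srl,flowering_date
sun-limestone,0.8,140,190
sun-basalt,0.6,128,182
shade-limestone,1,95,168
shade-basalt,0.9,95,165
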