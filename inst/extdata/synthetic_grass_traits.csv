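species_id,seed_mass,srl,flowering_date
Bouteloua_gracilis,0.3,210,213
Muhlenbergia_montana,0.1,180,224
Elymus_elymoides,3,95,166
Festuca_arizonica,1.1,80,181
Poa_fendleriana,0.35,85,152
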