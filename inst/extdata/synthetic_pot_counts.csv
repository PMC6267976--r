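sample_id,treatment,Bouteloua_gracilis,Muhlenbergia_montana,Elymus_elymoides,Festuca_arizonica,Poa_fendleriana
pot01,sun-limestone,5,2,1,2,5
pot02,sun-limestone,8,3,1,6,7
pot03,sun-limestone,6,2,0,3,6
pot04,sun-limestone,5,1,2,3,7
pot05,sun-limestone,5,2,3,3,5
pot06,sun-limestone,7,1,2,3,6
pot07,sun-limestone,6,1,0,5,2
pot08,sun-limestone,6,0,3,3,4
pot09,sun-limestone,5,2,1,2,5
pot10,sun-limestone,8,2,1,3,8
pot11,sun-limestone,7,0,2,3,4
pot12,sun-limestone,3,2,1,4,3
pot13,sun-limestone,6,2,2,2,6
pot14,sun-limestone,4,3,1,3,8
pot15,sun-limestone,2,1,1,3,5
pot16,sun-limestone,2,1,2,3,2
pot17,sun-limestone,6,1,2,4,5
pot18,sun-basalt,4,1,2,4,4
pot19,sun-basalt,4,4,2,4,7
pot20,sun-basalt,5,1,2,1,6
pot21,sun-basalt,4,1,2,1,5
pot22,sun-basalt,4,1,2,4,3
pot23,sun-basalt,4,2,1,3,6
pot24,sun-basalt,2,4,3,4,5
pot25,sun-basalt,5,0,2,3,5
pot26,sun-basalt,4,0,1,5,2
pot27,sun-basalt,7,2,3,3,6
pot28,sun-basalt,5,3,1,5,5
pot29,sun-basalt,5,1,2,5,5
pot30,sun-basalt,6,2,3,4,8
pot31,sun-basalt,5,3,2,2,4
pot32,sun-basalt,5,3,1,4,6
pot33,sun-basalt,3,1,4,1,3
pot34,sun-basalt,4,1,4,5,4
pot35,shade-limestone,3,0,2,5,6
pot36,shade-limestone,2,2,1,3,7
pot37,shade-limestone,2,1,3,4,6
pot38,shade-limestone,0,2,3,3,3
pot39,shade-limestone,1,1,1,4,7
pot40,shade-limestone,2,1,3,4,3
pot41,shade-limestone,3,1,1,8,6
pot42,shade-limestone,1,0,3,6,9
pot43,shade-limestone,0,2,1,5,5
pot44,shade-limestone,5,1,1,4,8
pot45,shade-limestone,3,4,1,6,4
pot46,shade-limestone,1,1,6,8,7
pot47,shade-limestone,2,0,2,6,6
pot48,shade-limestone,3,2,5,6,9
pot49,shade-limestone,2,3,2,5,6
pot50,shade-limestone,3,2,2,4,10
pot51,shade-basalt,2,3,2,3,8
pot52,shade-basalt,1,3,2,3,8
pot53,shade-basalt,3,1,1,6,9
pot54,shade-basalt,3,1,2,3,5
pot55,shade-basalt,2,3,4,4,10
pot56,shade-basalt,2,0,5,5,9
pot57,shade-basalt,0,3,2,3,9
pot58,shade-basalt,2,2,4,1,7
pot59,shade-basalt,2,3,0,2,7
pot60,shade-basalt,4,2,5,4,7
pot61,shade-basalt,3,3,2,5,9
pot62,shade-basalt,3,2,1,6,8
pot63,shade-basalt,2,2,5,3,6
pot64,shade-basalt,2,0,3,3,9
pot65,shade-basalt,1,1,4,5,4
pot66,shade-basalt,1,0,2,3,10
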