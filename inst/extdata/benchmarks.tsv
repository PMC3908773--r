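dataset	name	length	sequence	reference_contacts
I	S1	20	HPHPPHHPHPPHPHHPPHPH	23
I	S2	24	HHPPHPPHPPHPPHPPHPPHPPHH	23
I	S3	25	PPHPPHHPPPPHHPPPPHHPPPPHH	17
I	S4	36	PPPHHPPHHPPPPPHHHHHHHPPHHPPPPHHPPHPP	38
I	S5	48	PPHPHHHPHHHPPPPPHHHHHHHHHHPPPPPPHHPPHHPPHPPHHHHH	74
I	S6	50	HHPHPHPHPHHHHPHPPPHPPPHPPPPHPPPHPPPHPHHHHPHPHPHPHH	73
I	S7	60	PPHHHPHHHHHHHHPPPHHHHHHHHHHPHPPPHHHHHHHHHHHHPPPPHHHHHHPHHPHH	130
I	S8	64	HHHHHHHHHHHHPHPHPPHHPPHHPPHPPHHPPHHPPHPPHHPPHHPPHPHPHHHHHHHHHHHH	132
II	H1	48	HPHHPPHHHHPHHHPPHHPPHPHHHPHPHHPPHHPPPHPPPPPPPPHH	69
II	H2	48	HHHHPHHPHHHHHPPHPPHHPPHPPPPPPHPPHPPPHPPHHPPHHHPH	69
II	H3	48	PHPHHPHHHHHHPPHPHPPHPHHPHPHPPPHPPHHPPHHPPHPHPPHP	72
II	H4	48	PHPHHPPHPHHHPPHHPHHPPPHHHHHPPHPHHPHPHPPPPHPPHPHP	71
II	H5	48	PPHPPPHPHHHHPPHHHHPHHPHHHPPHPHPHPPHPPPPPPHHPHHPH	70
II	H6	48	HHHPPPHHPHPHHPHHPHHPHPPPPPPPHPHPPHPPPHPPHHHHHHPH	70
II	H7	48	PHPPPPHPHHHPHPHHHHPHHPHHPPPHPHPPPHHHPPHHPPHHPPPH	70
II	H8	48	PHHPHHHPHHHHPPHHHPPPPPPHPHHPPHHPHPPPHHPHPHPHHPPP	69
II	H9	48	PHPHPPPPHPHPHPPHPHHHHHHPPHHHPHPPHPHHPPHPHHHPPPPH	71
II	H10	48	PHHPPPPPPHHPPPHHHPHPPHPHHPPHPPHPPHHPPHHHHHHHPPHH	68
III	F90_1	90	PPHHHPPPHHPPPPHHPHHHHHHPHPHPHHPHHHHHPHHHPHPHHHHPHHPPPPHHHPHPHPPHHHPHHPHPHPPHHHPPPPHHPPHPPP	168
III	F90_2	90	PHHPPHPHHPHHHPHHHPPHHHHHHPPHPHPPPPHHHPHPPHHHHPHHHHPHHHPHHPPPPPHHPPPPHPHPHPHPHHPPHHHPPPHHHP	168
III	F90_3	90	HPHPHHHPHHHHPHHHPPPHPPPHPPPPHHHPPHPPPPHHHPPPPPPPPHPHHPHHHHPHHHPHPHHPPHHHHHPHHPPHHPHHHHHHPH	167
III	F90_4	90	PHHHPPHPPHPHPPPPHPPPHPHPPHPHHPHPPPHHHPHHHPPHHHPPHPPPPHPHHHPPHHPPHHHPPHHHHHHPHHHHHHHPHHHHPH	168
III	F90_5	90	PPPHPHHHHHHHPPPHPPHHHHHPHHPPHHPPHHHHPHPHPHHPPHHPPPPHPPPHHHPHPHHHHHHHPHHPHPPHHPPPHHHPHPPHPP	167
III	S1	135	HHHHPHHHHHHPPHHPHHHHHHHHPHHPHHHHHHHHHHPPHHPPPPPHHPHHHHHHHHPHPPHHPPPHHHHHHHHPHHHHHHPPHHHHHHHPHPPHHHHHHHHHPPHHPPPHHHHHHHPHHPHHHHHHHPPHHHH	357
III	S2	151	HHPPHPHHHHHHHHHHPHPPPPHHHPPPHHHHHPPHHHHHPPHHHHPPHHHHPPHHHHHHPHHHHPPPHHPPPHHHHHHHHPHPPHHHPPPHHHHHPPHHHHHHHPPPHHPPHHHHHPPPHHHHHHHHHPHPPHHHHHHHPPPHHHPPHHP	360
III	S3	161	HHHPPPHHPHHPPPPPHHHHHHHHPHPPHHPHHPHHHHHPPPHHHHHHHHHPPHPHPPHPHPPHHHPHPPHPHPPPHHHHHHPHHHHPPPHHHPPPPHHPPPHHHPPHHHHPHHHHHPPHHHHHHPPPHHHHHHPPPHPPHHHHPHHHHHHHPPHHPPHHH	367
III	S4	164	HHPPHPHHHHHHHPPHPHPPHPHPPPPHHHPPPHHPHPHHPPHHHHHPPHHHHPPHHHHPPHHHHHHPHHHHPPPHHPPPHHHHHHHHPHPPHHHPPPHHHHHPPHHHHHHPHPPPHHPPHHHPHHPPPHPHHHHHHHPHPPHPPHHHHHHPHPPPHHHPPHHP	370
III	R1	200	PPPHPHHPHHPPPHPHPPPPHPHHPPHPHHHHHPPHHPPHHHHHHPPHPPHHPPHPHPHHHHHPHHPHHHPPPHHHPHHPPHPHPPHPPPHPPHPPHPPHHHPHHHPHPPHPHHPHHHHPHPHHHPHHHPPPPPPHHHHHHPPPPPPPPHHHPPHPHPPPHPHPHPHHPPHHPPPPHHHHHHPPPHHPPPPPHPPPHHPP	384
III	R2	200	HPHHPPHPPPPPHHPHPHPHHPPHPPPPHHHHHHPPPHPPHHHPPHPPPPHHPPHHHPHPHHHPPHPHHPPHPHHPPPPHHPPHPPHHHHPPPPPHHHPPPPHPPPPPPHPPHHPHHHHPHHHHHHHHPPHHPPPHPHHHPHHHHHPHHPHHHPHPHHPPPPHPHHPHHHPHPPPPHPPPPPPHPHHHHHPHHPPPHPPH	383
III	R3	200	HPHHHPHHPHPHPPPHHHHHPHPHPHHHHPPPHHPPPPPPHHPPPPHPHHHPPPPHPPPHHPHHPPPHPPHPPPHHHHPHHPHPPPPHHPPPHHPPHPPPHPPHHHPHHHPHPPHPHHHHPPHHPPPPHHHPHHPPHPPHHHHPPHPHPPHPHPPPPPHPHPHHHHHHHPHPHHHHHHPHHPPPPHPPPPHPPPHHHPHH	385
III	F180_1	180	HHPPHHHHHPHHHPPPHHHPPHHHPHPPHHHHHPPPHHHPPPHPHHPPPPPHHPPHHPHHPHPHHPPPPPHHHPPPPHPHHHPPHPPPHHHPHHHHPPHHPHPHHHHPHHHHPPHHPHHPHHPHHHPHPPHPHHPHPHHPHHHPHHPPHPPPHPPPPPPPHHHPHHHHHPHHHHHPPHPP	NA
III	F180_2	180	PHHPHPPPHPPHHPHHHPHPHHPHHHPHHHPPPHHPPHPHPHHPHHHHPPHHPHPHHHHHPHHPPPPHPHPHPPHHHHPHHHHPHHHHHPPHPHHHPPPHPHPPHHPPPHHPHPHPPPPPHPHHPHHHPHPPPPHHPHHHHHPPPHHHHHHHHPHHPPPPPHPPPHPPHPPPHHPHHHHH	NA
III	F180_3	180	HHHPHPPHHPPPHPPPHPHPHPPHHHHPPHHHHHHPHPHHPPPPPHPPHHPHHHHHHHHHHHPPHPPHPPHHHHHHHHPPPPHPPHHHHHPPHHHPPHHPPHHHHHPPPHHHHHHPHHHPPPHHPPHPPPHPPHPPPHPPPPHHHPPHHPHPPHHHPHHPPHHPHHPHPHPHPHPHPHHP	378
IV	4BP2	123	PHHPHPPHHPHPHPPPPPHHPHPPHPHHHPHPPPPPPHPPHPPHHPPPPPHHPPPPPHPPHPHHHPPPHPPPHPHPHPPPPHPHPPPPPPHPPHHHPHPPPPPHHHPPHPHPPPPPPHPPPPH	NA
IV	2AAS	124	PPPPPPPHPPPPHPPPPPPPPPPPHHPPHHPPPPHPPPPHPPHPPHHPPPHPPHPPHHPPPPHPHPPPPPPHHPPHPPHPHPPHPPPPPPPHPPHPHPPPPPPPPHHHPHPPPPHHPHPHPPPH	NA
IV	5LYZ	129	PHHPPHPHPPPHPPPPHPPHPPHPHPPHHHPPPHPPPHPPPPPPPPPPPPPPHPHHPHPPPHHHPPPPPPPPPPHHPHPHPPHHPPPHPPPHPHPPPHHPPPPPHPPHHPHPPPHPPPPHPPHHPPHPH	NA
IV	9WGA	170	PHPPPPPPHPHPPPHHHPPHPHHPHPPPHHPPPHPPPPHHPPPPHPPPPPPPPHPPPPHHPPHPPHPHPPPHHPPPHPPPPHPPPHPHPPPPPPPHHPPPHHHPPHPHHPHPPPHHPPPHPPPPHPPPPPHPPPPPPPHHPPPHHHPPHPPHPHPPPHHPPPHPPPPHPP	NA
IV	1RBP	174	PPPHPHPPHPHPPPHPPPPHPPPHHPHPPPPPPPHHHPPPHHPPHPHPPPPPHPPPPPPPHPHHPPHPHHPPHHPPHPPPPPPPPHPHPHHPHPPHHPPPPPPPHHHPPPHPPHPHPHPHPHHPHPPPHPPPHPHHHPPPPPPHPPPPPPHHPPPPPPHHHPPPHPHHHPPPHH	NA
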