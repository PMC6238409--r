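mirna	mre_type	category
miR-455	8mer	high_confidence
miR-127	7mer-m8	high_confidence
miR-7a	7mer-m8	high_confidence
miR-7b	7mer-m8	high_confidence
miR-196a	7mer-m8	high_confidence
miR-298	7mer-m8	high_confidence
miR-421	7mer-m8	high_confidence
miR-497	7mer-m8	high_confidence
miR-124a	7mer-m8	high_confidence
miR-16	7mer-m8	high_confidence
miR-26a	7mer-m8	high_confidence
miR-26b	7mer-m8	high_confidence
miR-375	7mer-A1	high_confidence
miR-182	7mer-A1	high_confidence
miR-9	6mer	high_confidence
miR-186	6mer	high_confidence
miR-183	6mer	high_confidence
miR-494	8mer	low_confidence
miR-132	7mer-m8	low_confidence
miR-15b	7mer-m8	low_confidence
miR-195	7mer-m8	low_confidence
miR-376c	7mer-m8	low_confidence
miR-212	6mer	low_confidence
miR-340	6mer	low_confidence
miR-203	6mer	low_confidence
miR-187	7mer-m8	non_specific
miR-1187	7mer-m8	no_interaction
miR-15a	7mer-m8	no_interaction
miR-196b	7mer-m8	no_interaction
miR-365	7mer-m8	no_interaction
miR-466k	7mer-m8	no_interaction
miR-501-3p	7mer-m8	no_interaction
miR-96	7mer-A1	no_interaction
miR-101	6mer	no_interaction
miR-144	6mer	no_interaction
miR-362-3p	6mer	no_interaction
miR-410	6mer	no_interaction
miR-466f	6mer	no_interaction
miR-495	6mer	no_interaction
miR-335-3p	6mer	no_interaction
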