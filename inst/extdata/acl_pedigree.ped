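FamilyA	A_father	0	0	1	2	0
FamilyA	A_mother	0	0	2	1	0
FamilyA	A_twin1	A_father	A_mother	1	2	MZ_A
FamilyA	A_twin2	A_father	A_mother	1	2	MZ_A
FamilyA	A_brother	A_father	A_mother	1	2	0
FamilyB	B_father	0	0	1	1	0
FamilyB	B_mother	0	0	2	1	0
FamilyB	B_twin3	B_father	B_mother	1	2	MZ_B
FamilyB	B_twin4	B_father	B_mother	1	2	MZ_B
FamilyB	B_sister	B_father	B_mother	2	1	0
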