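system	antigen	ba_finnish_models_finnish_full	ba_finnish_models_danish_full	ba_danish_models_danish_full
ABO	A	0.999	0.995	0.999
ABO	A1	1.000	0.980	0.984
ABO	A2	0.981	0.894	0.891
ABO	AB	1.000	0.998	0.999
ABO	B	1.000	0.987	0.999
ABO	O	0.999	0.995	0.998
Cartwright	Yta	NA	NA	1.000
Cartwright	Ytb	1.000	0.998	0.998
Colton	Coa	1.000	0.833	0.833
Colton	Cob	0.988	0.926	0.963
Dombrock	Doa	1.000	0.999	0.999
Dombrock	Dob	1.000	0.999	0.999
Duffy	Fya	1.000	0.979	0.997
Duffy	Fyb	0.993	0.971	0.980
Gerbich	Lsa	0.917	NA	NA
HPA-1	HPA-1a	1.000	1.000	1.000
HPA-1	HPA-1b	0.986	0.939	0.999
Kell	K	1.000	0.916	0.956
Kell	k	NA	NA	0.838
Kell	Kpa	1.000	0.935	0.961
Kell	Kpb	NA	NA	0.750
Kell	Ula	1.000	NA	NA
Kidd	Jka	1.000	0.995	0.997
Kidd	Jkb	0.999	0.662	0.997
Knops	Kna	NA	NA	0.750
Knops	Knb	NA	NA	1.000
Landsteiner-Wiener	LWb	0.998	0.500	NA
Lewis	Lea	0.998	0.981	0.989
Lewis	Leb	0.968	0.729	0.736
Lutheran	Lua	0.988	0.956	0.964
Lutheran	Lub	NA	NA	0.828
MNS	M	0.984	0.970	0.993
MNS	N	0.988	0.947	0.987
MNS	S	1.000	0.995	0.997
MNS	s	1.000	0.988	0.993
P1PK	P1	0.984	0.500	0.965
Rh	C	0.989	0.646	0.997
Rh	c	0.997	0.500	0.997
Rh	Cw	0.999	0.918	0.953
Rh	Cx	0.997	NA	NA
Rh	D	0.988	0.784	0.997
Rh	E	0.998	0.992	0.995
Rh	e	0.988	0.982	0.984
Vel	Vel	NA	NA	0.811
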