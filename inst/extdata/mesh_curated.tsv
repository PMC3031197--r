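id	name	tree_numbers
D001	Body Regions	A01
D002	Extremities	A01.378
D003	Hand	A01.378.800
D004	Fingers	A01.378.800.667
D005	Thumb	A01.378.800.667.715
D006	Chemically-Induced Disorders	C25
D007	Substance-Related Disorders	C25.775;F03.900
D008	Alcoholism	C25.775.100;F03.900.100
D009	Mental Disorders	F03
D010	Psychiatry	H02.403.690
D011	Hospitals, Psychiatric	N02.278.421
D012	Statistics as Topic	E05.318.740
Q001	therapy
Q002	epidemiology
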