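sample_id	c0	c1	void_volume_V	soil_mass_m	duration_dt	temperature_T	soc
JC_natural_P1_D1	412	887	0.25	0.03	0.4166667	20	271
JC_natural_P1_D2	405	798	0.25	0.03	0.4166667	20	305
JC_cultivated_P1_D1	398	1243	0.25	0.03	0.4166667	20	164
JC_cultivated_P1_D2	401	1101	0.25	0.03	0.4166667	20	173
SP_natural_P1_D1	420	901	0.25	0.03	0.4166667	20	288
SP_cultivated_P1_D1	415	1310	0.25	0.03	0.4166667	20	152
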