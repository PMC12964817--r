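breed	phenotype	n_assemblies	n_carriers
Abondance	white	5	3
Hereford	white	1	1
Montbeliarde	white	6	5
Normande	white	8	7
Simmental	white	6	5
Aubrac	colored	7	0
Blonde d'Aquitaine	colored	4	0
Brown Swiss	colored	7	0
Charolaise	colored	4	0
Evolener	colored	1	0
Highland	colored	1	0
Holstein	colored	9	0
Limousine	colored	2	0
Parthenaise	colored	3	0
Rouge Flamande	colored	2	0
Tarentaise	colored	5	0
Vosgienne	colored	4	0
Yak	colored	1	0
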