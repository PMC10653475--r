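code_prefix,category,term_years
NCE,new_chemical_entity,5
NP,new_product,3
NC,new_combination,3
NPP,new_patient_population,3
NR,new_route,3
I,new_indication_or_dosing,3
D,new_indication_or_dosing,3
PED,pediatric,0.5
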