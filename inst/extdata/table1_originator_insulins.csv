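brand,ingredients,insulin_class,first_approval,n_products,n_device_combinations,manufacturer
Humalog,lispro,rapid,1996-06-14,4,3,ELI LILLY
Velosulin BR,human,rapid,1999-07-19,1,0,NOVO NORDISK
Novolog,aspart,rapid,2000-06-07,5,3,NOVO NORDISK
Apidra,glulisine,rapid,2004-04-16,3,1,SANOFI
Exubera,human,rapid,2006-01-27,2,2,PFIZER
Afrezza,human,rapid,2014-06-27,3,3,MANNKIND
Fiasp,aspart,rapid,2017-09-29,3,1,NOVO NORDISK
Humulin BR,regular,short,1986-04-28,1,0,ELI LILLY
Humulin U,regular,short,1987-06-10,2,0,ELI LILLY
Novolin L,regular,short,1991-06-25,1,0,NOVO NORDISK
Novolin R,regular,short,1991-06-25,1,1,NOVO NORDISK
Novolin N,NPH,intermediate,1991-07-01,1,1,NOVO NORDISK
Lantus,glargine,long,2000-04-20,2,1,SANOFI
Levemir,detemir,long,2005-06-16,5,4,NOVO NORDISK
Toujeo,glargine,long,2015-02-25,2,2,SANOFI
Tresiba,degludec,long,2015-09-25,3,1,NOVO NORDISK
Xultophy 100/3.6,glargine/lixisenatide,mixture_long_incretin,2016-11-21,1,1,NOVO NORDISK
Soliquo 100/33,glargine/lixisenatide,mixture_long_incretin,2016-11-21,1,1,SANOFI
Humalog 50/50,lispro protamine/lispro,mixture_intermediate_rapid,1999-12-22,3,2,ELI LILLY
Humalog 75/25,lispro protamine/lispro,mixture_intermediate_rapid,1999-12-22,3,2,ELI LILLY
Novolog 70/30,aspart protamine/aspart,mixture_intermediate_rapid,2001-11-01,4,1,NOVO NORDISK
Ryzodeg 70/30,degludec/aspart,mixture_intermediate_rapid,2015-09-25,1,1,NOVO NORDISK
Humulin 70/30,NPH/regular,mixture_intermediate_short,1989-04-25,2,1,ELI LILLY
Novolin 70/30,NPH/regular,mixture_intermediate_short,1991-06-25,1,1,NOVO NORDISK
Humulin 50/50,NPH/regular,mixture_intermediate_short,1992-04-29,1,0,ELI LILLY
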