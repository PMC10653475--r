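brand,ingredients,insulin_class,first_approval,n_products,n_device_combinations,manufacturer
Admelog,lispro,rapid,2017-12-11,3,1,SANOFI
Myxredlin,human,rapid,2019-06-20,1,0,BAXTER
Basaglar,glargine,long,2015-12-16,1,1,ELI LILLY
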