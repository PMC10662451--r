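biome,rf_inventory,rf_eo_modal,rf_eo_secondary,rf_eo_comparison,pct_diff_printed
Amazonia,0.48,0.59,0.24,0.59,23
Atlantic Forest,0.44,0.59,0.24,0.59,34
Cerrado,0.2,0.24,0.59,0.24,20
Pantanal,0.2,0.24,NA,0.24,20
Pampa,0.44,NA,0.59,0.59,34
Caatinga,0.1,0.95,NA,0.95,850
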