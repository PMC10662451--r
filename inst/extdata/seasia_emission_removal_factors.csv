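country,dataset,factor_type,label,value,value_min,value_max,unit,converted_from_biomass
indonesia,eo,primary_emission,country_average,197.7,NA,NA,MgC_per_ha,FALSE
indonesia,nghgi,primary_emission,dryland,176.6,NA,NA,MgC_per_ha,TRUE
indonesia,nghgi,primary_emission,swamp_forest,142.7,NA,NA,MgC_per_ha,TRUE
malaysia,eo,primary_emission,country_average,159.3,NA,NA,MgC_per_ha,FALSE
malaysia,nghgi,primary_emission,inland_state_land_forest,140,NA,NA,MgC_per_ha,FALSE
malaysia,nghgi,primary_emission,prf_inland,194,NA,NA,MgC_per_ha,FALSE
malaysia,eo,removal,old_growth,0.41,NA,NA,MgC_per_ha_per_yr,FALSE
malaysia,eo,removal,old_secondary_forest,1.60,NA,NA,MgC_per_ha_per_yr,FALSE
malaysia,eo,removal,young_secondary_forest,4.2,1.3,10.6,MgC_per_ha_per_yr,FALSE
malaysia,eo,removal,plantation_forest,NA,3.0,14.1,MgC_per_ha_per_yr,FALSE
malaysia,eo,removal,rubber,3.4,NA,NA,MgC_per_ha_per_yr,FALSE
malaysia,eo,removal,oil_palm,3.02,NA,NA,MgC_per_ha_per_yr,FALSE
malaysia,nghgi,removal,inland_forest,4.37,NA,NA,MgC_per_ha_per_yr,FALSE
malaysia,nghgi,removal,peat_swamp,4.32,NA,NA,MgC_per_ha_per_yr,FALSE
malaysia,nghgi,removal,state_land,2.02,NA,NA,MgC_per_ha_per_yr,FALSE
malaysia,nghgi,removal,plantation_forest,2.44,NA,NA,MgC_per_ha_per_yr,FALSE
malaysia,nghgi,removal,rubber,1.95,NA,NA,MgC_per_ha_per_yr,FALSE
malaysia,nghgi,removal,oil_palm,1.84,NA,NA,MgC_per_ha_per_yr,FALSE
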