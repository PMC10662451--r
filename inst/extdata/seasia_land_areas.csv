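country,dataset,land_type,wetness,land_group,area_kha
indonesia,eo,primary_dry_forest,dry,natural,72109.1
indonesia,eo,primary_swamp_forest,swamp,natural,9017.7
indonesia,eo,old_secondary_dry_forest,dry,natural,33168.4
indonesia,eo,old_secondary_swamp_forest,swamp,natural,5220.0
indonesia,eo,young_secondary_dry_forest,dry,natural,1772.8
indonesia,eo,young_secondary_swamp_forest,swamp,natural,197.5
indonesia,eo,forest_plantation,none,plantation,358.7
indonesia,eo,tree_plantation,none,plantation,26127.6
indonesia,eo,other_land,none,nonforest,40890.0
indonesia,nghgi,primary_dry_forest,dry,natural,41029
indonesia,nghgi,primary_swamp_forest,swamp,natural,4852
indonesia,nghgi,secondary_dry_forest,dry,natural,36469
indonesia,nghgi,secondary_swamp_forest,swamp,natural,6924
indonesia,nghgi,forest_plantation,none,plantation,5551
indonesia,nghgi,tree_plantation,none,plantation,20564
indonesia,nghgi,other_land,none,nonforest,76809
malaysia,eo,old_growth_forest,none,natural,12483.4
malaysia,eo,old_secondary_forest,none,natural,4595.9
malaysia,eo,young_secondary_forest,none,natural,361.9
malaysia,eo,forest_plantation,none,plantation,0.0
malaysia,eo,tree_plantation,none,plantation,10613.8
malaysia,eo,other_land,none,nonforest,4922.5
malaysia,nghgi,forest_land_remaining_forest_land,none,natural,17735.3
malaysia,nghgi,cropland_remaining_cropland,none,cropland,7037.9
malaysia,nghgi,forest_land_converted_to_cropland,none,cropland,0.85
malaysia,nghgi,settlement_remaining_settlement,none,settlement,2327.1
malaysia,nghgi,forest_land_converted_to_settlement,none,settlement,137.1
malaysia,nghgi,cropland_converted_to_settlement,none,settlement,21.9
malaysia,nghgi,grassland_remaining_grassland,none,grassland,313.0
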