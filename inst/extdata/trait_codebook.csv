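trait_name,category,trait_kind,rank
size_class,<200,ordinal,1
size_class,200-600,ordinal,2
size_class,>600,ordinal,3
feeding_type,microphagous,categorical,NA
feeding_type,raptorial_rotifer,categorical,NA
feeding_type,stationary_suspension,categorical,NA
feeding_type,tactile_raptorial,categorical,NA
feeding_type,D_filtration,categorical,NA
feeding_type,B_filtration,categorical,NA
feeding_type,C_filtration,categorical,NA
feeding_type,S_filtration,categorical,NA
trophic_group,herbivorous,categorical,NA
trophic_group,omnivorous,categorical,NA
trophic_group,carnivorous,categorical,NA
trophic_group,detritivorous,categorical,NA
habitat,littoral,categorical,NA
habitat,pelagic,categorical,NA
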