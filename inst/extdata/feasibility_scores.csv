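attribute,rosa_canina,sambucus_nigra,cornus_mas,amelanchier_ovalis
existing_cultivations,6,6,6,6
threat_category,1,1,1,0
protection_status,0,0,0,0
ex_situ_conservation,6,6,6,6
distribution,0,0,0,1
commercial_products,6,6,5,1
known_propagation,6,6,6,6
vegetative_propagation_success,6,6,6,6
seed_germination_success,6,5,0,0
cultivation_needs,6,6,6,6
existing_cultivation_protocols,6,6,6,5
water_demand,3,3,3,3
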