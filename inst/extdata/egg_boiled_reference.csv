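field,value
label,"Egg, boiled (hard or soft)"
food_id,egg_boiled
grams,44
price_usd_per_100g,0.35
energy_kcal_per_100g,155
protein_g_per_100g,12.6
choline_mg_per_100g,294
potassium_mg_per_100g,126
calcium_mg_per_100g,50
folate_mcg_per_100g,44
magnesium_mg_per_100g,10
zinc_mg_per_100g,1.05
vitamin_d_mcg_per_100g,2.2
vitamin_c_mg_per_100g,0
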