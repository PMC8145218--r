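indicator_id,subgroup_id,group_id
stunting_0_59m,Stunting,Child anthropometry
underweight_0_59m,Underweight,Child anthropometry
ate_4plus_food_groups,Ate 4+ food groups,Child diet
bottle_fed_yesterday,Bottle fed yesterday,Child diet
consumed_iron_rich_foods,Consumed iron-rich foods,Child diet
consumed_vita_rich_foods,Consumed vitamin A-rich foods,Child diet
continued_breastfeeding,Continued breastfeeding,Child diet
exclusive_breastfeeding_0_6m,Exclusive breastfeeding: 0-6 m,Child diet
early_initiation_breastfeeding,Initiation of breastfeeding within 1 hour of birth,Child diet
solid_foods_6_8m,Receiving solid semi-solid or soft foods: 6-8 m,Child diet
child_supplement_vaccine,Child took supplement/vaccine,Child health
diarrhea_last_2w,Diarrhea in last two weeks,Child health
diarrhea_last_2w_0_5m,Diarrhea in the last two weeks: 0-5 m,Child health
diarrhea_treatment,Received diarrhea treatment,Child health
diarrhea_more_to_drink,For those with diarrhea given more to drink,Child health
diarrhea_more_to_eat,For those with diarrhea given more to eat,Child health
ever_married,Individuals who have ever been married,HH characteristics
head_of_household_male,Head of household is male,HH characteristics
household_has_electricity,Household has electricity,HH characteristics
urban_residence,Urban residence,HH characteristics
household_has_car,Household has a car,HH wealth
household_has_land_bike_phone,Household has agricultural land/bike/phone,HH wealth
household_has_animals,Household has animals,HH wealth
woman_able_to_read,Woman able to read,Maternal characteristics
woman_never_attended_school,Woman never attended school,Maternal characteristics
facility_birth_sba,Birth at a health facility/assisted by a skilled birth attendant,Maternal health
woman_iron_supplements,Woman consumed/received iron supplements,Maternal health
anc_3plus_visits,Woman received antenatal care (ANC),Maternal health
woman_received_pnc,Woman received postnatal care (PNC),Maternal health
anc_content,Woman's antenatal care (ANC) content,Maternal health
handwash_station_supplies,Handwash station has ash/sand/soap/water,WASH
child_stool_disposed_safely,Household dispose child stool in toilet/latrine,WASH
improved_drinking_water,Household has improved drinking water,WASH
improved_sanitation,Household has improved sanitation,WASH
household_shares_toilet,Household shares toilet,WASH
household_treats_water,Household treats drinking water,WASH
water_30min_plus,30+ min for household to obtain drinking water,WASH
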