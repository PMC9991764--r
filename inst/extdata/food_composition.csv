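item_id,label,na_mg_per_100g,is_cooked_meal_or_salad,food_group,naffq_only
bread_white,White bread and rusks,500,0,cereals,0
breakfast_cereal,Breakfast cereals,400,0,cereals,0
rice_cooked,Rice (cooked),240,1,cereals,0
pasta_cooked,Pasta (cooked),200,1,cereals,0
potatoes_cooked,Potatoes (boiled or roast),180,1,vegetables,0
legumes_cooked,Legumes (cooked),230,1,legumes,0
vegetables_raw_salad,Raw vegetable salad,60,1,vegetables,0
vegetables_boiled_salad,Boiled vegetable salad,70,1,vegetables,0
fruit_fresh,Fresh fruit,2,0,fruits,0
milk,Milk,45,0,dairy,0
yogurt,Yogurt,55,0,dairy,0
cheese_feta,Feta cheese,1100,0,dairy,0
cheese_soft,Soft unsalted cheese,300,0,dairy,0
red_meat_cooked,Red meat (cooked),350,1,meat,0
white_meat_cooked,Poultry (cooked),330,1,meat,0
fish_cooked,Fish and seafood (cooked),380,1,fish,0
cold_cuts,Cold cuts and processed meat,1050,0,meat,0
eggs,Eggs,130,0,eggs,0
traditional_dish,Traditional composite dishes,400,1,composite,0
homemade_pie,Home-made pies,450,1,composite,0
olives,Olives,1550,0,added_fats,0
olive_oil,Olive oil,1,0,added_fats,0
butter_unsalted,Unsalted butter and margarine,10,0,added_fats,0
sweets,Sweets and desserts,150,0,sweets,0
salty_snacks,Salty snacks,800,0,snacks,0
soft_drinks,Soft drinks,10,0,beverages,0
coffee_tea,Coffee and tea,5,0,beverages,0
alcoholic_beverages,Alcoholic beverages,10,0,beverages,0
butter_salted,Salted butter and margarine,580,0,added_fats,1
cheese_rich_na,Sodium-rich cheeses (roquefort parmesan edam gouda gruyere),1450,0,dairy,1
crackers_salty,Salty crackers and biscuits,700,0,snacks,1
canned_fish,Canned fish and seafood,400,0,fish,1
tomato_juice_refined,Refined tomato juice,250,0,beverages,1
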