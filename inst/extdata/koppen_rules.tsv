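rule	threshold	units	meaning
polar_family_hottest_max	10	deg C	hottest month at or below this -> polar (E) family
tundra_hottest_min	0	deg C	polar family: hottest month above this -> ET, else EF
temperate_coldest_min	0	deg C	coldest month above this -> temperate (C), else continental (D)
hot_summer_a	22	deg C	hottest month at or above this -> third letter a
warm_summer_b_months	4	months	at least this many months at or above 10 C -> third letter b
warm_summer_b_temp	10	deg C	month threshold counted for the b rule
dry_summer_s_abs	40	mm	driest summer month below this (and below wettest winter month / 3) -> s
dry_summer_s_ratio	3	ratio	wettest-winter to driest-summer ratio for the s rule
dry_winter_w_ratio	10	ratio	wettest-summer to driest-winter ratio for the w rule
summer_months	4-9	months	northern-hemisphere summer (April-September)
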