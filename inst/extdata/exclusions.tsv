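intervention_name	outcome_name	section	primary_reason	quality	source
Periconceptual folic acid fortification	Child mortality due to neural tube defects	wra_pw	no_outcome_proportion_data	very_low	Blencowe 2018
Zinc fortification	Preterm birth	wra_pw	no_significant_effect	low	Carducci 2021
Omega-3 fatty acid supplementation	Preterm birth	wra_pw	no_significant_effect	moderate	Middleton 2018
Vitamin D supplementation	Preterm birth	wra_pw	no_significant_effect	low	Palacios 2018
Stop smoking education	Preterm birth	wra_pw	unable_to_model	moderate	Chamberlain 2017
Deworming	Maternal anaemia	wra_pw	no_significant_effect	low	Salam 2021
Calcium supplementation	Pre-eclampsia	wra_pw	double_counted_elsewhere	low	Hofmeyr 2018
Thiamine supplementation	Neonatal mortality	wra_pw	no_systematic_review		NA
Nutrition sensitive agriculture intervention	Appropriate complementary feeding	child	no_standard_definition	very_low	Margolies 2022
Provision of SQ-LNS	Child anaemia	child	no_mortality_link	moderate	Wessells 2021
Multiple micronutrient powder	Child anaemia	child	no_mortality_link	moderate	Suchdev 2020; De-regil 2017
Iron fortification	Child anaemia	child	no_mortality_link	very_low	Keats 2019
Deworming	Wasting	child	no_significant_effect	very_low	Thayer 2017
Prophylactic antibiotics	Stunting	child	no_systematic_review		NA
Vitamin D supplementation	Pneumonia incidence	child	no_significant_effect	low	Martineau 2017
Vitamin D supplementation	Stunting	child	no_significant_effect	low	Huey 2020
Neonatal zinc supplementation	Neonatal mortality due to sepsis	child	small_sample	very_low	Irfan 2022
Zinc for treatment of sepsis	Neonatal mortality due to sepsis	child	small_sample	very_low	Irfan 2022
Provision of SQ-LNS	Child mortality	child	no_direct_estimate	moderate	Stewart 2020
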