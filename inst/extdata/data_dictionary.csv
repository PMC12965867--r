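column,type,units,levels,description
id,identifier,,,unique participant identifier
age,continuous,years,,age at screening (time-fixed)
race,categorical,,aian|asian|black|white|multi,self-reported race (NIH categories; aian/asian/multi collapsed to `other` for modelling)
hispanic,binary,,0|1,Hispanic/Latino ethnicity
income,categorical,,lt35k|35to75k|ge75k,total family household income bracket
educ,categorical,,hs_or_less|some_college|college|graduate,highest educational attainment
marital,categorical,,never|divorced|widowed|married|marriage_like,marital status (marriage_like collapsed to married for modelling)
sleep,categorical,,le5|h6|h7|h8|ge9,usual sleep duration (hours per night)
diabetes,binary,,0|1,ever diagnosed with diabetes
cancer,binary,,0|1,ever diagnosed with cancer (excluding melanoma)
smoking0,categorical,,never|former|current,smoking status at enrollment (year 0)
smoking1,categorical,,never|former|current,smoking status at baseline (year 3)
hei0,continuous,score,,diet-quality index at enrollment
hei1,continuous,score,,diet-quality index at baseline
alcohol0,continuous,servings/week,,alcohol intake at enrollment
alcohol1,continuous,servings/week,,alcohol intake at baseline
met0,continuous,MET-h/week,,physical activity at enrollment
met1,continuous,MET-h/week,,physical activity at baseline
cesd0,continuous,score 0-1,,depressive-symptom score at enrollment
cesd1,continuous,score 0-1,,depressive-symptom score at baseline
energy0,continuous,kcal/day,,total energy intake at enrollment
energy1,continuous,kcal/day,,total energy intake at baseline (eligibility: 500-5000 kcal retained)
grams0,continuous,g/day,,total protein intake at enrollment
grams1,continuous,g/day,,total protein intake at baseline
a0,continuous,g/kg/day,,protein per kg body weight at enrollment (grams0 / weight0)
a1,continuous,g/kg/day,,protein per kg body weight at baseline (grams1 / weight1) -- the exposure
vat0,continuous,cm2,,visceral adipose tissue area at enrollment
vat1,continuous,cm2,,visceral adipose tissue area at baseline
vat2,continuous,cm2,,visceral adipose tissue area at end of follow-up (year 6; missing iff censored)
sat0,continuous,cm2,,abdominal subcutaneous adipose tissue at enrollment
sat1,continuous,cm2,,abdominal subcutaneous adipose tissue at baseline
sat2,continuous,cm2,,abdominal subcutaneous adipose tissue at end of follow-up
fatpct0,continuous,%,,total body fat percentage at enrollment
fatpct1,continuous,%,,total body fat percentage at baseline
fatpct2,continuous,%,,total body fat percentage at end of follow-up
leanpct0,continuous,%,,lean soft tissue mass percentage at enrollment
leanpct1,continuous,%,,lean soft tissue mass percentage at baseline
leanpct2,continuous,%,,lean soft tissue mass percentage at end of follow-up
weight0,continuous,kg,,body weight at enrollment
weight1,continuous,kg,,body weight at baseline
weight2,continuous,kg,,body weight at end of follow-up
censor,categorical,,none|death|ltfu,censoring status before the end-of-follow-up measurement
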