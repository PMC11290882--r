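canonical_name,dose_value,dose_unit,unit_price,tier
amoxicillin,250,mg,0.03,primary
amoxicillin,500,mg,0.04,primary
amoxicillin,500,mg,0.28,indicative
co-amoxiclav,375,mg,0.09,primary
co-amoxiclav,625,mg,0.11,primary
co-amoxiclav,1200,mg,1.25,indicative
piperacillin-tazobactam,2250,mg,3.80,primary
piperacillin-tazobactam,4500,mg,5.10,primary
piperacillin-tazobactam,4500,mg,9.75,indicative
doxycycline,50,mg,0.06,primary
doxycycline,100,mg,0.07,primary
doxycycline,100,mg,0.49,indicative
clarithromycin,250,mg,0.12,primary
clarithromycin,500,mg,0.16,primary
clarithromycin,500,mg,1.63,indicative
azithromycin,250,mg,0.32,primary
azithromycin,500,mg,0.55,primary
erythromycin,250,mg,0.21,primary
erythromycin,500,mg,0.37,primary
ceftriaxone,1000,mg,0.95,primary
ceftriaxone,2000,mg,1.75,primary
ceftriaxone,1000,mg,9.58,indicative
cefuroxime,250,mg,0.30,primary
cefuroxime,750,mg,0.88,primary
cefuroxime,1500,mg,1.55,primary
cefotaxime,1000,mg,1.90,primary
cefotaxime,2000,mg,3.40,primary
ceftazidime,1000,mg,2.20,primary
ceftazidime,2000,mg,4.05,primary
meropenem,500,mg,2.65,primary
meropenem,1000,mg,4.20,primary
meropenem,1000,mg,13.12,indicative
ertapenem,1000,mg,31.50,indicative
vancomycin,500,mg,2.40,primary
vancomycin,1000,mg,4.10,primary
vancomycin,1000,mg,8.36,indicative
teicoplanin,200,mg,4.60,primary
teicoplanin,400,mg,7.90,primary
gentamicin,80,mg,1.40,primary
gentamicin,240,mg,2.10,primary
gentamicin,360,mg,3.15,indicative
amikacin,500,mg,4.30,indicative
ciprofloxacin,250,mg,0.05,primary
ciprofloxacin,500,mg,0.07,primary
ciprofloxacin,500,mg,0.86,indicative
levofloxacin,250,mg,0.31,primary
levofloxacin,500,mg,0.44,primary
moxifloxacin,400,mg,0.78,primary
metronidazole,200,mg,0.05,primary
metronidazole,400,mg,0.06,primary
metronidazole,500,mg,0.72,indicative
flucloxacillin,250,mg,0.08,primary
flucloxacillin,500,mg,0.10,primary
flucloxacillin,1000,mg,1.85,indicative
benzylpenicillin,600,mg,1.10,primary
benzylpenicillin,1200,mg,1.95,primary
trimethoprim,100,mg,0.04,primary
trimethoprim,200,mg,0.05,primary
co-trimoxazole,480,mg,0.18,primary
co-trimoxazole,960,mg,0.26,primary
linezolid,600,mg,2.95,primary
linezolid,600,mg,44.50,indicative
clindamycin,150,mg,0.24,primary
clindamycin,300,mg,0.41,primary
nitrofurantoin,50,mg,0.11,primary
nitrofurantoin,100,mg,0.14,primary
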