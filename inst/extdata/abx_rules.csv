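pattern,canonical,action
^(paracetamol|acetaminophen|ibuprofen|aspirin)$,,block
^(dexamethasone|prednisolone|hydrocortisone)$,,block
^(remdesivir|oseltamivir|tamiflu|aciclovir|acyclovir)$,,block
^(enoxaparin|clexane|dalteparin|heparin)$,,block
^(omeprazole|lansoprazole|salbutamol|furosemide|frusemide)$,,block
^(fluconazole|nystatin|amphotericin b?)$,,block
^(chlorphenamine|codeine|morphine|insulin)$,,block
^amox(y|i)?(cillin)?$,amoxicillin,map
^amoxycillin$,amoxicillin,map
^co-? ?amox(iclav)?$,co-amoxiclav,map
^augmentin$,co-amoxiclav,map
^(pip-? ?tazo?|tazocin)$,piperacillin-tazobactam,map
^piperacillin[ /-]?(with )?tazobactam$,piperacillin-tazobactam,map
^dox(y|ycycline)?$,doxycycline,map
^clarithro(mycin)?$,clarithromycin,map
^klaricid$,clarithromycin,map
^azithro(mycin)?$,azithromycin,map
^zithromax$,azithromycin,map
^erythro(mycin)?$,erythromycin,map
^ceftriax(one)?$,ceftriaxone,map
^rocephin$,ceftriaxone,map
^cefurox(ime)?$,cefuroxime,map
^zinacef$,cefuroxime,map
^cefotax(ime)?$,cefotaxime,map
^ceftaz(idime)?$,ceftazidime,map
^mero(penem)?$,meropenem,map
^erta(penem)?$,ertapenem,map
^vanc(o|omycin)?$,vancomycin,map
^teic(o|oplanin)?$,teicoplanin,map
^gent(a|amicin|amycin)?$,gentamicin,map
^amikacin$,amikacin,map
^cipro(floxacin)?$,ciprofloxacin,map
^levoflox(acin)?$,levofloxacin,map
^tavanic$,levofloxacin,map
^moxiflox(acin)?$,moxifloxacin,map
^metro(nidazole)?$,metronidazole,map
^flagyl$,metronidazole,map
^fluclox(acillin)?$,flucloxacillin,map
^(benpen|benzyl ?penicillin|penicillin g)$,benzylpenicillin,map
^trimethoprim$,trimethoprim,map
^co-? ?trim(oxazole)?$,co-trimoxazole,map
^septrin$,co-trimoxazole,map
^linezolid$,linezolid,map
^zyvox$,linezolid,map
^clinda(mycin)?$,clindamycin,map
^nitrofurantoin$,nitrofurantoin,map
^macrobid$,nitrofurantoin,map
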