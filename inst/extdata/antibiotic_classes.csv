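compound,class
streptomycin,Aminoglycosides
kanamycin,Aminoglycosides
neomycin,Aminoglycosides
gentamicin,Aminoglycosides
amikacin,Aminoglycosides
imipenem,Carbapenems
meropenem,Carbapenems
ciprofloxacin,Fluoroquinolones
norfloxacin,Fluoroquinolones
levofloxacin,Fluoroquinolones
ampicillin,Penicillins
penicillin-G,Penicillins
carbenicillin,Penicillins
amoxicillin,Penicillins
tetracycline,Tetracyclines
doxycycline,Tetracyclines
chlortetracycline,Tetracyclines
cefotaxime,Cephalosporins
ceftazidime,Cephalosporins
cephalexin,Cephalosporins
erythromycin,Macrolides
azithromycin,Macrolides
polymyxin-B,Polypeptides
bacitracin,Polypeptides
vancomycin,Polypeptides
rifampicin,Rifamycins
nitrofurantoin,Nitrofurans
furazolidone,Nitrofurans
nystatin,Antifungal Agents
amphotericin-B,Antifungal Agents
cycloheximide,Antifungal Agents
chloramphenicol,Others
trimethoprim,Others
sulfamethoxazole,Others
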