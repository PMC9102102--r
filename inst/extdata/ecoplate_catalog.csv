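substrate,code,guild
Water,W,W
Pyruvic acid methyl ester,CH1,CH
Tween 40,P1,P
Tween 80,P2,P
alpha-Cyclodextrin,P3,P
Glycogen,P4,P
d-Cellobiose,CH2,CH
alpha-d-Lactose,CH3,CH
beta-Methyl-d-glucoside,CH4,CH
d-Xylose,CH5,CH
i-Erythritol,CH6,CH
d-Mannitol,CH7,CH
N-Acetyl-d-glucosamine,CH8,CH
d-Glucosaminic acid,CX1,CX
Glucose-1-phosphate,CH9,CH
"d,l-alpha-Glycerol phosphate",CH10,CH
d-Galactonic acid gamma-lactone,CX2,CX
d-Galacturonic acid,CX3,CX
2-Hydroxy benzoic acid,CX4,CX
4-Hydroxy benzoic acid,CX5,CX
gamma-Hydroxy butyric acid,CX6,CX
Itaconic acid,CX7,CX
alpha-Keto butyric acid,CX8,CX
d-Malic acid,CX9,CX
l-Arginine,AA1,AA
l-Asparagine,AA2,AA
l-Phenylalanine,AA3,AA
l-Serine,AA4,AA
l-Threonine,AA5,AA
Glycyl-l-glutamic acid,AA6,AA
Phenylethylamine,AM1,AM
Putrescine,AM2,AM
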