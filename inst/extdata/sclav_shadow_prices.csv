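metabolite,batch,fedbatch,pathway
alpha-ketoglutarate,0,0.05,Glycolysis and TCA cycle
Pyruvate,0,0.02,Glycolysis and TCA cycle
Citrate,0,0.05,Glycolysis and TCA cycle
Isocitrate,0,0.05,Glycolysis and TCA cycle
Fumarate,0,0.02,Glycolysis and TCA cycle
Acetate,0,0.02,Glycolysis and TCA cycle
Succinate,0,0.02,Glycolysis and TCA cycle
Oxaloacetate,0,0.02,Glycolysis and TCA cycle
Malate,0,0.02,Glycolysis and TCA cycle
Erythrose 4 phosphate,0,-0.40,Pentose phosphate pathway
Fructose 6 phosphate,0,-0.38,Pentose phosphate pathway
Xylulose 5 phosphate,0,-0.39,Pentose phosphate pathway
Sedoheptulose 7-phosphate,0,-0.37,Pentose phosphate pathway
L-glutamate,0.5,0.05,Amino acids synthesis
L-glutamin,0.5,0.05,Amino acids synthesis
L-arginine,1.5,0.05,Amino acids synthesis
L-asparagin,0.5,0.02,Amino acids synthesis
L-aspartate,0.5,0.02,Amino acids synthesis
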