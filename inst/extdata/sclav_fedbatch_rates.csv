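phase,reaction,fba,exp,exp_sd
batch,Growth,0.042,0.042,0.004
batch,O2,-0.512,-1.350,NA
batch,Glycerol,-0.182,-0.182,NA
batch,CO2,0.639,1.640,NA
batch,Clavulanate,0.002,0.002,NA
batch,Succinate,0.014,0.014,NA
batch,Oxaloacetate,0.004,0.004,NA
batch,Malate,0.000,0.001,NA
batch,Pyruvate,0.000,0.000,NA
batch,Acetate,0.000,0.000,NA
fedbatch,Growth,0.031,0.031,0.003
fedbatch,O2,-0.776,-1.200,NA
fedbatch,Glycerol,-0.457,-0.470,NA
fedbatch,CO2,0.610,1.400,NA
fedbatch,Clavulanate,0.004,0.004,NA
fedbatch,Succinate,0.257,0.007,NA
fedbatch,Oxaloacetate,0.000,0.003,NA
fedbatch,Malate,0.000,0.000,NA
fedbatch,Pyruvate,0.038,0.005,NA
fedbatch,Acetate,0.000,0.000,NA
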