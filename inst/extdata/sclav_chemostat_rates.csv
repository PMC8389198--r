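dilution_rate,reaction,fba,exp
0.045,Growth,0.039,0.045
0.045,O2,-0.375,-1.665
0.045,Glycerol,-0.695,-1.110
0.045,CO2,0.067,0.067
0.045,Clavulanate,0.017,0.398
0.045,Phosphate,0.000,NA
0.045,Glutamate,-0.350,NA
0.035,Growth,0.034,0.035
0.035,O2,-0.322,-1.621
0.035,Glycerol,-0.639,-0.968
0.035,CO2,0.023,0.023
0.035,Clavulanate,0.015,0.357
0.035,Phosphate,0.000,NA
0.035,Glutamate,-0.310,NA
0.050,Growth,0.044,0.050
0.050,O2,-0.511,-1.848
0.050,Glycerol,-0.728,-0.728
0.050,CO2,0.253,0.253
0.050,Clavulanate,0.020,0.435
0.050,Phosphate,0.000,NA
0.050,Glutamate,-0.400,NA
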