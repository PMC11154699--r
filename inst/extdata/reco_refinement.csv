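class,experiment,nu,tau,kappa,reference_source
Grassland,SM,1545.8,NA,3.9,FLUXNET
Cropland,SM,7997.9,NA,0.2,FLUXNET
Savanna,SM,9770.4,NA,-0.1,FLUXNET
Shrubland,SM,4390.4,NA,0.6,FLUXNET
DeciduousForest,SM,10059.1,NA,-0.03,FLUXNET
EvergreenForest,SM,7147.7,NA,0.5,FLUXNET
MixedForest,SM,7488.6,NA,0.3,FLUXNET
Grassland,ST,NA,0.002,3.9,FLUXNET
Cropland,ST,NA,0.009,0.4,FLUXNET
Savanna,ST,NA,0.01,-0.09,FLUXNET
Shrubland,ST,NA,0.003,0.9,FLUXNET
DeciduousForest,ST,NA,0.01,0.01,FLUXNET
EvergreenForest,ST,NA,0.01,0.4,FLUXNET
MixedForest,ST,NA,0.01,0.4,FLUXNET
Grassland,SMST,2790.4,-0.0023,3.96,FLUXNET
Cropland,SMST,8588.3,-0.0008,0.2,FLUXNET
Savanna,SMST,10321.2,-0.0009,-0.07,FLUXNET
Shrubland,SMST,5059.4,-0.001,0.72,FLUXNET
DeciduousForest,SMST,11684.6,-0.003,0.02,FLUXNET
EvergreenForest,SMST,4505.6,0.005,0.44,FLUXNET
MixedForest,SMST,10214.6,-0.005,0.3,FLUXNET
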