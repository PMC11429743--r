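team,rank,genetics,weather,soil,environment_covariates,field_management,experimental_design,other_factors
CLAC,1,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
igorkf,2,FALSE,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
phenomaize,3,TRUE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
UCD_MegaLMM,4,TRUE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
CGM,5,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
Purdue,6,TRUE,TRUE,TRUE,FALSE,FALSE,TRUE,FALSE
SmAL,7,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
ML_APT,8,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
MPB_Group,9,TRUE,TRUE,TRUE,FALSE,TRUE,FALSE,TRUE
AIBreeding,10,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
AgroStat,11,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE
arulrich,12,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE
DataJanitors,13,TRUE,FALSE,FALSE,TRUE,TRUE,TRUE,FALSE
CropsAreCool,14,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
AllModelsAreWrong,15,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,TRUE
agAdaptAR,16,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,TRUE
DeepCropVision,18,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE
supermanwasd,19,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
BioSense,20,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
Kernel of Truth,21,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE
AIMaize,24,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
EnBiSys,25,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
Genetwister,26,TRUE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE
gartybois,27,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE
Niche Squad,28,TRUE,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE
uwaBioinfo,29,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE
TinyAfrica,30,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,TRUE
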