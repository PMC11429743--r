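team,rank,classical_ml,linear_mixed_blup,deep_learning,other_strategy,ensemble
CLAC,1,TRUE,TRUE,FALSE,FALSE,TRUE
igorkf,2,TRUE,FALSE,FALSE,FALSE,FALSE
phenomaize,3,FALSE,TRUE,FALSE,FALSE,FALSE
UCD_MegaLMM,4,FALSE,TRUE,FALSE,FALSE,FALSE
CGM,5,FALSE,TRUE,FALSE,FALSE,FALSE
Purdue,6,TRUE,TRUE,FALSE,FALSE,TRUE
SmAL,7,FALSE,FALSE,TRUE,TRUE,FALSE
ML_APT,8,TRUE,TRUE,FALSE,FALSE,TRUE
MPB_Group,9,FALSE,TRUE,TRUE,FALSE,FALSE
AIBreeding,10,TRUE,TRUE,TRUE,FALSE,TRUE
AgroStat,11,TRUE,FALSE,FALSE,FALSE,TRUE
arulrich,12,TRUE,FALSE,FALSE,FALSE,FALSE
DataJanitors,13,TRUE,TRUE,FALSE,FALSE,TRUE
CropsAreCool,14,TRUE,FALSE,FALSE,FALSE,TRUE
AllModelsAreWrong,15,TRUE,TRUE,FALSE,FALSE,TRUE
agAdaptAR,16,TRUE,FALSE,TRUE,FALSE,TRUE
DeepCropVision,18,FALSE,FALSE,TRUE,FALSE,TRUE
supermanwasd,19,FALSE,FALSE,FALSE,FALSE,TRUE
BioSense,20,TRUE,FALSE,FALSE,TRUE,FALSE
Kernel of Truth,21,TRUE,TRUE,FALSE,FALSE,TRUE
AIMaize,24,TRUE,TRUE,TRUE,FALSE,TRUE
EnBiSys,25,FALSE,FALSE,TRUE,FALSE,FALSE
Genetwister,26,FALSE,TRUE,FALSE,FALSE,FALSE
gartybois,27,TRUE,TRUE,FALSE,FALSE,FALSE
Niche Squad,28,FALSE,FALSE,TRUE,FALSE,FALSE
uwaBioinfo,29,TRUE,FALSE,FALSE,FALSE,TRUE
TinyAfrica,30,TRUE,FALSE,TRUE,FALSE,FALSE
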