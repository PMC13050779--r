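parcel_id,network
L_mPFC,DMN
R_mPFC,DMN
L_PCC,DMN
R_PCC,DMN
L_Precuneus,DMN
R_Precuneus,DMN
L_AngularG,DMN
R_AngularG,DMN
L_MTG,DMN
R_MTG,DMN
L_Parahipp,DMN
R_Parahipp,DMN
L_dlPFC,TPN
R_dlPFC,TPN
L_FEF,TPN
R_FEF,TPN
L_IPS,TPN
R_IPS,TPN
L_SPL,TPN
R_SPL,TPN
L_MT,TPN
R_MT,TPN
L_preSMA,TPN
R_preSMA,TPN
L_dPMC,TPN
R_dPMC,TPN
L_aInsula,SN
R_aInsula,SN
L_dACC,SN
R_dACC,SN
L_FrOperc,SN
R_FrOperc,SN
L_SMG,SN
R_SMG,SN
L_V1,Other
R_V1,Other
L_V2,Other
R_V2,Other
L_A1,Other
R_A1,Other
L_S1,Other
R_S1,Other
L_M1,Other
R_M1,Other
L_TempPole,Other
R_TempPole,Other
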