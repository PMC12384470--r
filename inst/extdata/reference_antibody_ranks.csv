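parameter,RSPH4A,DNAH5,GAS8,RSPH9,SPEF2,CCDC40,DNALI1,CCDC39
Correlation_RWC_RED_GREEN,1,2,3,4,5,6,7,8
AreaShape_Compactness,1,2,3,4,5,6,7,8
AreaShape_Area,1,2,3,4,5,6,7,8
AreaShape_Eccentricity,3,6,4,2,1,7,5,8
Intensity_MassDisplacement,1,2,3,4,5,8,7,6
Distance_Centroid_mCilia,4,1,2,3,5,6,7,8
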