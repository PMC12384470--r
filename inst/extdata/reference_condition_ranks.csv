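parameter,-80_28d,-20_28d,-20/RT/-80,-20_8w,4/RT/-80,RT/RT/-80,RT_28d
Correlation_RWC_RED_GREEN,1,2,5,4,3,6,7
AreaShape_Compactness,1,2,3,4,5,6,7
AreaShape_Area,1,2,4,3,5,6,7
AreaShape_Eccentricity,1,2,3,5,4,6,7
Intensity_MassDisplacement,1,3,2,5,4,7,6
Distance_Centroid_mCilia,1,2,4,3,5,7,6
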