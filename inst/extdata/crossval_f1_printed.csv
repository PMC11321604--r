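analysis,label,effect,lower,upper
main,philips,0.81,0.77,0.84
main,leica,0.71,0.65,0.78
main,3dhistech,0.76,0.72,0.80
main,hamamatsu,0.80,0.78,0.83
normalization_only,philips,0.80,0.77,0.84
normalization_only,leica,0.70,0.64,0.76
normalization_only,3dhistech,0.74,0.70,0.79
normalization_only,hamamatsu,0.81,0.78,0.83
augmentation_only,philips,0.81,0.77,0.84
augmentation_only,leica,0.70,0.64,0.76
augmentation_only,3dhistech,0.55,0.47,0.64
augmentation_only,hamamatsu,0.79,0.77,0.82
neither,philips,0.80,0.77,0.84
neither,leica,0.69,0.63,0.75
neither,3dhistech,0.56,0.48,0.65
neither,hamamatsu,0.78,0.76,0.81
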