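domain,model,unweighted_paf,communality,weighted_paf
socioeconomic status,1,1.47,20.45,0.66
medical history,1,8.15,32.41,4.64
psychosocial factors,1,11.02,39.50,6.93
physical measures,1,9.26,23.39,4.48
lifestyles,1,9.27,18.27,3.96
socioeconomic status,2,6.30,14.20,2.37
medical history,2,12.57,22.44,5.96
psychosocial factors,2,15.03,38.62,9.34
physical measures,2,18.14,34.26,10.62
lifestyles,2,12.60,19.59,5.58
overall,1,NA,NA,20.67
overall,2,NA,NA,33.87
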