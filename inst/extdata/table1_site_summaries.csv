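variable,group,n,mean,sd
symptom_onset_years,Canada,46,17.75,11.98
symptom_onset_years,Australia_I,58,22.95,9.78
symptom_onset_years,Australia_II,44,23.84,7.22
education_years,Canada,52,13.15,3.08
education_years,Australia_I,81,14.07,3.25
education_years,Australia_II,55,12.96,1.85
age_years,Canada,54,38.59,9.23
age_years,Australia_I,88,42.44,11.17
age_years,Australia_II,56,41.98,11.46
panss_positive,Canada,52,17.62,6.5
panss_positive,Australia_I,85,15.71,5.13
panss_positive,Australia_II,55,15.73,4.72
panss_negative,Canada,54,21.7,5.38
panss_negative,Australia_I,88,14.86,6.32
panss_negative,Australia_II,56,15.43,4.97
panss_general,Canada,54,36.39,7.46
panss_general,Australia_I,88,30.24,8.57
panss_general,Australia_II,56,30.57,6.68
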