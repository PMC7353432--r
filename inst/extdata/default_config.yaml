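cells:
- cohort: 4-10
  gender: male
  n_participants: 414
  intake_mean_nonsupp: 2.03
  intake_sd_nonsupp: 0.33
  supplement_prevalence: 0.159420289855072
  supp_dose_mean: 3.89
  supp_dose_sd: 2.679757451710882
  rtec_consumer_fraction: 0.893719806763285
  rtec_mean_g: 31.0
  rtec_sd_g: 18.599999999999998
  blood_sample_fraction: 0.2
- cohort: 4-10
  gender: female
  n_participants: 389
  intake_mean_nonsupp: 1.89
  intake_sd_nonsupp: 1.08
  supplement_prevalence: 0.136246786632391
  supp_dose_mean: 5.38
  supp_dose_sd: 10.574994089832865
  rtec_consumer_fraction: 0.868894601542416
  rtec_mean_g: 29.0
  rtec_sd_g: 17.399999999999999
  blood_sample_fraction: 0.2
- cohort: 11-18
  gender: male
  n_participants: 445
  intake_mean_nonsupp: 2.35
  intake_sd_nonsupp: 1.3
  supplement_prevalence: 0.060674157303371
  supp_dose_mean: 3.76
  supp_dose_sd: 3.044026938119964
  rtec_consumer_fraction: 0.689887640449438
  rtec_mean_g: 40.0
  rtec_sd_g: 24.0
  blood_sample_fraction: 0.35
- cohort: 11-18
  gender: female
  n_participants: 439
  intake_mean_nonsupp: 1.9
  intake_sd_nonsupp: 1.21
  supplement_prevalence: 0.052391799544419
  supp_dose_mean: 4.140000000000001
  supp_dose_sd: 2.233271143412729
  rtec_consumer_fraction: 0.662870159453303
  rtec_mean_g: 31.0
  rtec_sd_g: 18.599999999999998
  blood_sample_fraction: 0.35
- cohort: 19-64
  gender: male
  n_participants: 710
  intake_mean_nonsupp: 3.13
  intake_sd_nonsupp: 2.18
  supplement_prevalence: 0.136619718309859
  supp_dose_mean: 6.3
  supp_dose_sd: 8.060403215720664
  rtec_consumer_fraction: 0.6
  rtec_mean_g: 42.0
  rtec_sd_g: 25.199999999999999
  blood_sample_fraction: 0.47
- cohort: 19-64
  gender: female
  n_participants: 945
  intake_mean_nonsupp: 2.5
  intake_sd_nonsupp: 1.8
  supplement_prevalence: 0.186243386243386
  supp_dose_mean: 5.3
  supp_dose_sd: 3.549704213029587
  rtec_consumer_fraction: 0.641269841269841
  rtec_mean_g: 38.0
  rtec_sd_g: 22.800000000000001
  blood_sample_fraction: 0.47
- cohort: 65plus
  gender: male
  n_participants: 191
  intake_mean_nonsupp: 3.85
  intake_sd_nonsupp: 2.57
  supplement_prevalence: 0.235602094240838
  supp_dose_mean: 4.99
  supp_dose_sd: 4.68088666814312
  rtec_consumer_fraction: 0.680628272251309
  rtec_mean_g: 72.0
  rtec_sd_g: 43.199999999999996
  blood_sample_fraction: 0.47
- cohort: 65plus
  gender: female
  n_participants: 237
  intake_mean_nonsupp: 2.76
  intake_sd_nonsupp: 1.57
  supplement_prevalence: 0.324894514767932
  supp_dose_mean: 6.970000000000001
  supp_dose_sd: 5.187629516455469
  rtec_consumer_fraction: 0.79746835443038
  rtec_mean_g: 60.0
  rtec_sd_g: 36.0
  blood_sample_fraction: 0.47
dose_response_params:
- cohort: 4-10
  a: 21.379999999999999
  b: 30.77
  c: 2.42
- cohort: 11-18
  a: 36.149999999999999
  b: 17.609999999999999
  c: 0.34
- cohort: 19-64
  a: 35.780000000000001
  b: 20.260000000000002
  c: 0.2
- cohort: 65plus
  a: 27.100000000000001
  b: 55.920000000000002
  c: 0.07
seasonal_params:
- cohort: 4-10
  gender: male
  alpha: -0.76
  beta: 10.970000000000001
  gamma: 22.710000000000001
- cohort: 4-10
  gender: female
  alpha: -0.43
  beta: 7.8
  gamma: 24.079999999999998
- cohort: 11-18
  gender: male
  alpha: -0.86
  beta: 13.130000000000001
  gamma: 7.49
- cohort: 11-18
  gender: female
  alpha: -0.46
  beta: 6.94
  gamma: 23.09
- cohort: 19-64
  gender: male
  alpha: -0.65
  beta: 10.58
  gamma: 10.380000000000001
- cohort: 19-64
  gender: female
  alpha: -0.53
  beta: 8.35
  gamma: 21.16
- cohort: 65plus
  gender: male
  alpha: -0.34
  beta: 5.25
  gamma: 30.68
- cohort: 65plus
  gender: female
  alpha: -0.47
  beta: 6.87
  gamma: 23.140000000000001
serum_noise_sd:
  4-10: 19.883908396235356
  11-18: 22.437007012219119
  19-64: 22.612069795560103
  65plus: 19.468858700797071
n_psu: 36
n_strata: 9
seed: 1
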