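arm,tissue,metric,mean_diff,sd_diff,p_wilcoxon,wcv_pct,rc_upper_pct,rc_lower_pct
test_retest,MBP,suv_max,0.01,0.38,0.808,10.33,31.35,-23.87
test_retest,MBP,suv_mean,0.02,0.25,0.961,10.20,30.88,-23.59
test_retest,MBP,suv_peak,-0.01,0.27,0.884,9.56,28.81,-22.36
test_retest,LV,suv_max,1.37,8.04,0.711,69.02,328.34,-76.65
test_retest,LV,suv_mean,1.33,4.73,0.528,64.68,298.53,-74.91
test_retest,LV,suv_peak,1.47,5.68,0.586,63.63,291.54,-74.46
test_retest,BM,suv_max,-0.13,0.77,0.833,18.55,60.27,-37.61
test_retest,BM,suv_mean,-0.004,0.44,0.408,14.85,46.80,-31.88
test_retest,BM,suv_peak,-0.08,0.44,0.615,11.31,34.59,-25.70
test_retest,SM_right,suv_max,-0.08,0.29,0.189,23.39,79.08,-44.16
test_retest,SM_right,suv_mean,-0.03,0.10,0.306,15.45,48.91,-32.85
test_retest,SM_right,suv_peak,-0.03,0.13,0.638,15.35,48.55,-32.68
test_retest,SM_left,suv_max,-0.10,0.32,0.445,21.56,71.81,-41.79
test_retest,SM_left,suv_mean,-0.02,0.12,0.685,15.74,49.94,-33.31
test_retest,SM_left,suv_peak,-0.02,0.14,0.638,15.15,47.83,-32.36
test_retest,lung_RUZ,suv_max,-0.20,0.36,0.039,28.24,99.26,-49.81
test_retest,lung_RUZ,suv_mean,0.02,0.06,0.215,10.58,32.16,-24.33
test_retest,lung_RUZ,suv_peak,0.01,0.27,0.679,27.70,96.92,-49.22
test_retest,lung_RMZ,suv_max,-0.20,0.36,0.808,25.39,87.23,-46.59
test_retest,lung_RMZ,suv_mean,0.02,0.06,0.178,9.85,29.75,-22.93
test_retest,lung_RMZ,suv_peak,0.01,0.27,0.426,17.19,55.21,-35.57
test_retest,lung_RLZ,suv_max,0.01,0.51,0.783,22.22,74.39,-42.66
test_retest,lung_RLZ,suv_mean,0.02,0.07,0.131,10.53,31.97,-24.23
test_retest,lung_RLZ,suv_peak,0.11,0.36,0.291,17.80,57.47,-36.50
test_retest,lung_LUZ,suv_max,-0.09,0.54,0.737,31.27,112.58,-52.96
test_retest,lung_LUZ,suv_mean,0.01,0.06,0.433,12.67,39.20,-28.16
test_retest,lung_LUZ,suv_peak,0.01,0.21,0.654,19.48,63.77,-38.94
test_retest,lung_LMZ,suv_max,-0.08,0.29,0.191,16.88,54.09,-35.10
test_retest,lung_LMZ,suv_mean,0.01,0.07,0.411,15.10,47.68,-32.29
test_retest,lung_LMZ,suv_peak,-0.07,0.24,0.247,18.98,61.88,-38.23
test_retest,lung_LLZ,suv_max,-0.01,0.36,0.986,18.85,61.38,-38.04
test_retest,lung_LLZ,suv_mean,0.03,0.10,0.192,18.48,60.01,-37.51
test_retest,lung_LLZ,suv_peak,0.09,0.26,0.122,15.40,48.73,-32.77
interobserver,MBP,suv_max,0.08,0.45,0.961,10.85,33.06,-24.85
interobserver,MBP,suv_mean,0.01,0.18,0.884,6.10,17.84,-15.14
interobserver,MBP,suv_peak,0.01,0.18,0.808,5.41,15.72,-13.58
interobserver,LV,suv_max,0.15,2.00,0.397,20.29,66.89,-40.08
interobserver,LV,suv_mean,-0.28,1.18,0.943,21.61,72.01,-41.87
interobserver,LV,suv_peak,0.13,1.57,0.363,16.78,53.71,-34.94
interobserver,BM,suv_max,-0.01,0.19,0.654,5.26,15.26,-13.24
interobserver,BM,suv_mean,-0.04,0.17,0.884,7.05,20.77,-17.20
interobserver,BM,suv_peak,0,0.09,0.852,3.06,8.70,-8.00
interobserver,SM_right,suv_max,0.09,0.24,0.123,17.26,55.47,-35.68
interobserver,SM_right,suv_mean,-0.02,0.09,0.131,9.94,30.04,-23.10
interobserver,SM_right,suv_peak,0,0.11,0.783,10.28,31.17,-23.76
interobserver,SM_left,suv_max,-0.01,0.18,0.884,12.66,39.16,-28.14
interobserver,SM_left,suv_mean,-0.04,0.08,0.020,8.12,24.16,-19.46
interobserver,SM_left,suv_peak,-0.03,0.07,0.101,6.85,20.16,-16.78
interobserver,lung_RUZ,suv_max,-0.06,0.36,0.629,33.10,120.88,-54.72
interobserver,lung_RUZ,suv_mean,-0.02,0.05,0.126,10.52,31.95,-24.22
interobserver,lung_RUZ,suv_peak,-0.04,0.35,0.968,36.47,136.75,-57.76
interobserver,lung_RMZ,suv_max,-0.12,0.49,0.291,25.05,85.83,-46.19
interobserver,lung_RMZ,suv_mean,0,0.05,0.485,7.60,22.48,-18.35
interobserver,lung_RMZ,suv_peak,-0.11,0.34,0.178,24.47,83.44,-45.49
interobserver,lung_RLZ,suv_max,0.03,0.26,0.543,15.67,49.71,-33.20
interobserver,lung_RLZ,suv_mean,0,0.04,0.758,6.12,17.90,-15.18
interobserver,lung_RLZ,suv_peak,0.02,0.29,0.638,21.90,73.14,-42.24
interobserver,lung_LUZ,suv_max,-0.03,0.35,0.478,22.28,74.63,-42.74
interobserver,lung_LUZ,suv_mean,-0.01,0.05,0.455,9.42,28.35,-22.09
interobserver,lung_LUZ,suv_peak,-0.06,0.22,0.391,18.72,60.89,-37.85
interobserver,lung_LMZ,suv_max,-0.09,0.36,0.263,20.85,69.04,-40.84
interobserver,lung_LMZ,suv_mean,0,0.03,0.502,4.78,13.81,-12.14
interobserver,lung_LMZ,suv_peak,-0.13,0.32,0.086,20.17,66.40,-39.90
interobserver,lung_LLZ,suv_max,-0.12,0.32,0.159,15.84,50.31,-33.47
interobserver,lung_LLZ,suv_mean,-0.01,0.03,0.131,4.77,13.78,-12.11
interobserver,lung_LLZ,suv_peak,-0.13,0.38,0.192,19.78,64.92,-39.37
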