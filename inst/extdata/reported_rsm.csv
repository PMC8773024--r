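response,term,value,p_value
y_pv_pct,intercept,284.3,0.000
y_pv_pct,pressure,-3.594,0.075
y_pv_pct,co2_flow,-2.204,0.019
y_pv_pct,pressure2,0.01215,0.000
y_pv_pct,pressure:co2_flow,0.01620,0.006
y_pv_pct,r_squared_pct,88.28,
y_pv_pct,s,4.42,
y_dv_pct,intercept,-40.3,0.000
y_dv_pct,pressure,1.241,0.000
y_dv_pct,co2_flow,-1.691,0.833
y_dv_pct,pressure2,-0.00493,0.035
y_dv_pct,co2_flow2,0.00898,0.105
y_dv_pct,pressure:co2_flow,0.00900,0.058
y_dv_pct,r_squared_pct,91.26,
y_dv_pct,s,4.00,
y_saf_pct,intercept,242.6,0.000
y_saf_pct,pressure,-2.343,0.000
y_saf_pct,co2_flow,-3.835,0.003
y_saf_pct,pressure2,0.00717,0.001
y_saf_pct,co2_flow2,0.00812,0.040
y_saf_pct,pressure:co2_flow,0.02520,0.000
y_saf_pct,r_squared_pct,96.74,
y_saf_pct,s,2.66,
e_cha_pv,intercept,-3.889,0.000
e_cha_pv,pressure,0.0796,0.026
e_cha_pv,co2_flow,0.0253,0.381
e_cha_pv,pressure2,-0.000314,0.001
e_cha_pv,co2_flow2,-0.000395,0.034
e_cha_pv,r_squared_pct,83.00,
e_cha_pv,s,0.13,
e_fa_pv,intercept,-4.11,0.000
e_fa_pv,pressure,0.0835,0.003
e_fa_pv,co2_flow,0.0160,0.454
e_fa_pv,pressure2,-0.000315,0.002
e_fa_pv,co2_flow2,-0.000262,0.189
e_fa_pv,r_squared_pct,82.91,
e_fa_pv,s,0.15,
e_all_pv,intercept,-3.840,0.000
e_all_pv,pressure,0.0802,0.004
e_all_pv,co2_flow,0.0166,0.479
e_all_pv,pressure2,-0.000308,0.001
e_all_pv,co2_flow2,-0.000264,0.125
e_all_pv,r_squared_pct,84.54,
e_all_pv,s,0.13,
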