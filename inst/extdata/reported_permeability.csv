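compound,r_sc,r_sg,r_ss,r_sb,r_cells,r_skin,log_kp_pred,log_kp_corrected,log_kp_calc_epidermis,log_kp_caco2
CAF,4.07e7,1.22e7,2.09e7,3.72e6,7.75e7,7.74e7,-5.89,-7.01,-6.85,-5.84
CHA,1.76e8,5.13e8,1.16e9,8.06e7,1.93e9,1.86e9,-7.27,-8.39,,-5.60
FA,3.23e7,1.61e6,2.88e6,6.29e5,3.74e7,3.74e7,-5.57,-6.69,-7.15,-4.98
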