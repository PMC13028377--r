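variable,units,bias,random_error,loa_low,loa_high,rmse,icc_3_1
avg_runway_velocity,m/s,0.00,0.04,-0.04,0.04,0.02,1.000
max_runway_velocity,m/s,-0.08,0.10,-0.18,0.02,0.09,0.993
step_length_3rd_last,m,0.00,0.02,-0.03,0.02,0.01,0.997
step_velocity_3rd_last,m/s,0.01,0.10,-0.09,0.11,0.05,0.998
step_length_2nd_last,m,0.00,0.01,-0.01,0.01,0.01,0.999
step_velocity_2nd_last,m/s,0.00,0.06,-0.06,0.06,0.03,0.999
step_length_last,m,0.00,0.01,-0.01,0.01,0.01,0.999
step_velocity_last,m/s,-0.02,0.05,-0.07,0.04,0.03,0.999
cm_height_pp,m,0.02,0.01,0.00,0.03,0.02,0.943
cm_hor_velocity_pp,m/s,0.02,0.21,-0.19,0.23,0.10,0.991
cm_vert_velocity_pp,m/s,-0.06,0.29,-0.35,0.23,0.15,0.969
standing_height,m,0.01,0.01,0.00,0.02,0.01,0.980
dl_hip_angle_to,deg,-4.19,11.85,-16.03,7.66,7.04,0.920
dl_knee_angle_to,deg,-3.01,14.24,-17.25,11.23,7.43,0.773
dl_ankle_angle_to,deg,3.28,12.35,-9.07,15.64,6.75,0.763
tol_hip_angle_to,deg,-8.67,6.44,-15.11,-2.23,9.20,0.340
tol_knee_angle_to,deg,-3.15,7.21,-10.35,4.06,4.66,0.410
tol_ankle_angle_to,deg,9.01,7.91,1.10,16.92,9.77,0.280
cm_hor_velocity_to,m/s,0.07,0.16,-0.08,0.23,0.10,0.988
cm_vert_velocity_to,m/s,-0.03,0.23,-0.26,0.21,0.11,0.898
cm_abs_velocity_to,m/s,0.06,0.19,-0.13,0.25,0.11,0.980
cm_takeoff_angle,deg,-0.42,1.68,-2.09,1.26,0.90,0.790
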