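variable,units,group,ref_mean,ref_sd,ml_mean,ml_sd
avg_runway_velocity,m/s,ALL,8.96,0.77,8.96,0.78
max_runway_velocity,m/s,ALL,9.21,0.79,9.29,0.78
step_length_3rd_last,m,ALL,2.09,0.13,2.09,0.14
step_velocity_3rd_last,m/s,ALL,8.92,0.78,8.92,0.81
step_length_2nd_last,m,ALL,2.06,0.19,2.06,0.18
step_velocity_2nd_last,m/s,ALL,8.96,0.79,8.96,0.78
step_length_last,m,ALL,1.89,0.17,1.89,0.18
step_velocity_last,m/s,ALL,9.01,0.74,9.03,0.75
cm_height_pp,m,ALL,1.09,0.05,1.07,0.06
cm_hor_velocity_pp,m/s,ALL,8.38,0.75,8.35,0.80
cm_vert_velocity_pp,m/s,ALL,0.84,0.64,0.90,0.58
standing_height,m,ALL,1.21,0.06,1.20,0.06
dl_hip_angle_to,deg,ALL,141.43,16.81,145.61,17.92
dl_knee_angle_to,deg,ALL,55.38,10.58,58.39,11.37
dl_ankle_angle_to,deg,ALL,122.45,9.08,119.16,10.19
tol_hip_angle_to,deg,ALL,194.15,4.35,202.82,5.96
tol_knee_angle_to,deg,ALL,167.25,4.09,170.40,3.45
tol_ankle_angle_to,deg,ALL,131.74,6.06,122.73,4.08
cm_hor_velocity_to,m/s,ALL,7.45,0.67,7.37,0.66
cm_vert_velocity_to,m/s,ALL,2.48,0.29,2.50,0.21
cm_abs_velocity_to,m/s,ALL,7.85,0.70,7.79,0.66
cm_takeoff_angle,deg,ALL,18.38,1.25,18.80,1.52
avg_runway_velocity,m/s,MEN,9.63,0.28,9.64,0.28
max_runway_velocity,m/s,MEN,9.90,0.29,9.97,0.30
step_length_3rd_last,m,MEN,2.20,0.08,2.20,0.10
step_velocity_3rd_last,m/s,MEN,9.60,0.30,9.61,0.30
step_length_2nd_last,m,MEN,2.20,0.12,2.20,0.11
step_velocity_2nd_last,m/s,MEN,9.63,0.31,9.63,0.30
step_length_last,m,MEN,1.96,0.15,1.97,0.16
step_velocity_last,m/s,MEN,9.66,0.26,9.68,0.24
cm_height_pp,m,MEN,1.12,0.02,1.11,0.02
cm_hor_velocity_pp,m/s,MEN,8.92,0.48,8.93,0.52
cm_vert_velocity_pp,m/s,MEN,1.11,0.68,1.11,0.64
standing_height,m,MEN,1.25,0.02,1.24,0.02
dl_hip_angle_to,deg,MEN,140.06,13.13,141.39,14.92
dl_knee_angle_to,deg,MEN,59.82,9.90,58.96,13.17
dl_ankle_angle_to,deg,MEN,120.39,8.98,121.26,6.65
tol_hip_angle_to,deg,MEN,193.35,5.84,204.59,5.98
tol_knee_angle_to,deg,MEN,168.02,5.76,170.52,3.33
tol_ankle_angle_to,deg,MEN,133.11,4.51,122.95,4.28
cm_hor_velocity_to,m/s,MEN,8.02,0.24,7.90,0.29
cm_vert_velocity_to,m/s,MEN,2.70,0.19,2.64,0.22
cm_abs_velocity_to,m/s,MEN,8.46,0.23,8.34,0.26
cm_takeoff_angle,deg,MEN,18.61,1.47,18.47,1.74
avg_runway_velocity,m/s,WOMEN,8.30,0.35,8.29,0.37
max_runway_velocity,m/s,WOMEN,8.53,0.32,8.61,0.34
step_length_3rd_last,m,WOMEN,1.98,0.04,1.98,0.05
step_velocity_3rd_last,m/s,WOMEN,8.25,0.36,8.22,0.41
step_length_2nd_last,m,WOMEN,1.92,0.13,1.92,0.12
step_velocity_2nd_last,m/s,WOMEN,8.29,0.38,8.29,0.38
step_length_last,m,WOMEN,1.81,0.18,1.82,0.18
step_velocity_last,m/s,WOMEN,8.36,0.31,8.37,0.33
cm_height_pp,m,WOMEN,1.06,0.06,1.04,0.06
cm_hor_velocity_pp,m/s,WOMEN,7.83,0.53,7.78,0.59
cm_vert_velocity_pp,m/s,WOMEN,0.57,0.55,0.69,0.50
standing_height,m,WOMEN,1.18,0.06,1.17,0.06
dl_hip_angle_to,deg,WOMEN,142.80,21.96,149.84,21.90
dl_knee_angle_to,deg,WOMEN,50.95,10.54,57.83,11.29
dl_ankle_angle_to,deg,WOMEN,124.50,10.03,117.06,13.65
tol_hip_angle_to,deg,WOMEN,194.35,3.13,201.04,6.23
tol_knee_angle_to,deg,WOMEN,166.49,2.10,170.28,4.08
tol_ankle_angle_to,deg,WOMEN,130.37,7.77,122.51,4.51
cm_hor_velocity_to,m/s,WOMEN,6.88,0.36,6.85,0.42
cm_vert_velocity_to,m/s,WOMEN,2.26,0.16,2.37,0.10
cm_abs_velocity_to,m/s,WOMEN,7.25,0.37,7.25,0.39
cm_takeoff_angle,deg,WOMEN,18.16,1.17,19.13,1.44
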