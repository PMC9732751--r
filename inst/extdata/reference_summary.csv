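arm,variable,n,mean,sd,median,q1,q3
telemedicine,treatment_duration_min,26,8.23,4.45,6.00,5,10
telemedicine,one_way_distance_km,26,37.00,32.06,30.00,10,46.25
telemedicine,travel_time_min,26,38.46,21.72,40.00,18.75,46.25
telemedicine,waiting_time_min,26,6.73,6.84,5.00,1.75,10
telemedicine,total_time_min,26,21.92,10.40,22.50,13.75,30
control,treatment_duration_min,25,10.92,5.58,10.00,8,14.5
control,one_way_distance_km,25,31.58,22.62,28.00,15.5,45
control,travel_time_min,25,34.80,20.89,30.00,20,40
control,waiting_time_min,24,36.88,27.54,30.00,15,48.75
control,total_time_min,25,154.80,79.75,150.00,105,197.5
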