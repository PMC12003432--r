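group,posture,n,force_mean_N,force_sd_N,moment_mean_Nm,moment_sd_Nm
lumpectomy,external_rotation,9,57.5,21.1,14.1,5.4
lumpectomy,internal_rotation,9,74.8,21.0,18.3,5.4
lumpectomy,horizontal_adduction,9,82.7,16.5,28.1,5.6
lumpectomy,horizontal_abduction,9,83.4,24.6,28.4,7.9
lumpectomy,elevation,9,77.1,30.3,26.3,10.2
implant,external_rotation,9,53.7,13.1,13.0,3.6
implant,internal_rotation,9,61.0,22.2,14.8,5.8
implant,horizontal_adduction,9,67.9,18.1,24.9,7.2
implant,horizontal_abduction,9,64.8,18.7,23.9,7.5
implant,elevation,9,77.8,31.0,28.8,12.3
flap,external_rotation,7,66.6,22.2,15.5,5.3
flap,internal_rotation,7,76.4,26.0,17.7,6.1
flap,horizontal_adduction,7,74.5,25.2,26.4,7.7
flap,horizontal_abduction,7,93.6,19.0,33.5,6.1
flap,elevation,7,95.0,40.6,33.9,13.4
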