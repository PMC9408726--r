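definition_id,metric,duration,threshold_type,intensity,coastal_threshold_c,coastal_hw_days,coastal_aic,piedmont_threshold_c,piedmont_hw_days,piedmont_aic
HW_01,mean,2+,relative,99,29.16,33,4475.7,28.40,29,4817.9
HW_02,mean,3+,relative,99,29.16,25,4480.7,28.40,21,4843.0
HW_03,mean,2+,relative,98,28.57,58,4362.9,27.66,61,4778.4
HW_04,mean,3+,relative,98,28.57,46,4396.7,27.66,49,4796.9
HW_05,mean,2+,relative,95,27.65,105,4287.3,26.70,136,4629.7
HW_06,mean,3+,relative,95,27.65,97,4293.5,26.70,118,4656.9
HW_07,mean,2+,relative,90,26.65,217,4216.2,25.63,241,4547.9
HW_08,mean,3+,relative,90,26.65,195,4211.8,25.63,227,4551.8
HW_09,max,2+,relative,99,35.04,22,4475.4,35.52,20,4842.6
HW_10,max,3+,relative,99,35.04,16,4479.7,35.52,14,4852.4
HW_11,max,2+,relative,98,34.31,38,4413.7,34.69,38,4799.8
HW_12,max,3+,relative,98,34.31,30,4435.3,34.69,32,4813.2
HW_13,max,2+,relative,95,33.13,98,4283.5,33.30,109,4665.9
HW_14,max,3+,relative,95,33.13,80,4318.0,33.30,85,4716.0
HW_15,max,2+,relative,90,31.97,190,4192.6,31.94,194,4583.4
HW_16,max,3+,relative,90,31.97,168,4234.4,31.94,180,4615.9
HW_17,max,1-day,absolute,35,35.00,26,4423.1,35.00,34,4801
HW_18,min,2+,relative,99,23.86,29,4488.1,21.86,45,4810.3
HW_19,min,3+,relative,99,23.86,25,4479.1,21.86,31,4831.9
HW_20,min,2+,relative,98,23.36,56,4401.1,21.40,83,4783.6
HW_21,min,3+,relative,98,23.36,46,4433.5,21.40,65,4799.5
HW_22,min,2+,relative,95,22.57,108,4352.0,20.63,156,4722.0
HW_23,min,3+,relative,95,22.57,94,4353.0,20.63,136,4722.6
HW_24,min,2+,relative,90,21.64,223,4305.5,19.72,265,4670.3
HW_25,min,3+,relative,90,21.64,199,4303.0,19.72,235,4693.7
HW_26,apparent_max,1-day,relative,95,37.21,36,4254.0,35.26,27,4659.0
HW_27,apparent_max,1-day,relative,90,36.20,71,4319.9,35.92,58,4749.8
HW_28,apparent_max,1-day,relative,85,35.47,106,4415.7,36.95,98,4799.1
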