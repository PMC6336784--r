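group_id,treatment,id,sex,role
control_g001,control,control_g001_focal,male,focal
control_g001,control,control_g001_rival1,male,rival
control_g001,control,control_g001_rival2,male,rival
control_g001,control,control_g001_rival3,male,rival
control_g001,control,control_g001_female1,female,female
control_g001,control,control_g001_female2,female,female
control_g001,control,control_g001_female3,female,female
control_g001,control,control_g001_female4,female,female
control_g002,control,control_g002_focal,male,focal
control_g002,control,control_g002_rival1,male,rival
control_g002,control,control_g002_rival2,male,rival
control_g002,control,control_g002_rival3,male,rival
control_g002,control,control_g002_female1,female,female
control_g002,control,control_g002_female2,female,female
control_g002,control,control_g002_female3,female,female
control_g002,control,control_g002_female4,female,female
control_g003,control,control_g003_focal,male,focal
control_g003,control,control_g003_rival1,male,rival
control_g003,control,control_g003_rival2,male,rival
control_g003,control,control_g003_rival3,male,rival
control_g003,control,control_g003_female1,female,female
control_g003,control,control_g003_female2,female,female
control_g003,control,control_g003_female3,female,female
control_g003,control,control_g003_female4,female,female
control_g004,control,control_g004_focal,male,focal
control_g004,control,control_g004_rival1,male,rival
control_g004,control,control_g004_rival2,male,rival
control_g004,control,control_g004_rival3,male,rival
control_g004,control,control_g004_female1,female,female
control_g004,control,control_g004_female2,female,female
control_g004,control,control_g004_female3,female,female
control_g004,control,control_g004_female4,female,female
control_g005,control,control_g005_focal,male,focal
control_g005,control,control_g005_rival1,male,rival
control_g005,control,control_g005_rival2,male,rival
control_g005,control,control_g005_rival3,male,rival
control_g005,control,control_g005_female1,female,female
control_g005,control,control_g005_female2,female,female
control_g005,control,control_g005_female3,female,female
control_g005,control,control_g005_female4,female,female
control_g006,control,control_g006_focal,male,focal
control_g006,control,control_g006_rival1,male,rival
control_g006,control,control_g006_rival2,male,rival
control_g006,control,control_g006_rival3,male,rival
control_g006,control,control_g006_female1,female,female
control_g006,control,control_g006_female2,female,female
control_g006,control,control_g006_female3,female,female
control_g006,control,control_g006_female4,female,female
high_polyandry_g001,high_polyandry,high_polyandry_g001_focal,male,focal
high_polyandry_g001,high_polyandry,high_polyandry_g001_rival1,male,rival
high_polyandry_g001,high_polyandry,high_polyandry_g001_rival2,male,rival
high_polyandry_g001,high_polyandry,high_polyandry_g001_rival3,male,rival
high_polyandry_g001,high_polyandry,high_polyandry_g001_female1,female,female
high_polyandry_g001,high_polyandry,high_polyandry_g001_female2,female,female
high_polyandry_g001,high_polyandry,high_polyandry_g001_female3,female,female
high_polyandry_g001,high_polyandry,high_polyandry_g001_female4,female,female
high_polyandry_g002,high_polyandry,high_polyandry_g002_focal,male,focal
high_polyandry_g002,high_polyandry,high_polyandry_g002_rival1,male,rival
high_polyandry_g002,high_polyandry,high_polyandry_g002_rival2,male,rival
high_polyandry_g002,high_polyandry,high_polyandry_g002_rival3,male,rival
high_polyandry_g002,high_polyandry,high_polyandry_g002_female1,female,female
high_polyandry_g002,high_polyandry,high_polyandry_g002_female2,female,female
high_polyandry_g002,high_polyandry,high_polyandry_g002_female3,female,female
high_polyandry_g002,high_polyandry,high_polyandry_g002_female4,female,female
high_polyandry_g003,high_polyandry,high_polyandry_g003_focal,male,focal
high_polyandry_g003,high_polyandry,high_polyandry_g003_rival1,male,rival
high_polyandry_g003,high_polyandry,high_polyandry_g003_rival2,male,rival
high_polyandry_g003,high_polyandry,high_polyandry_g003_rival3,male,rival
high_polyandry_g003,high_polyandry,high_polyandry_g003_female1,female,female
high_polyandry_g003,high_polyandry,high_polyandry_g003_female2,female,female
high_polyandry_g003,high_polyandry,high_polyandry_g003_female3,female,female
high_polyandry_g003,high_polyandry,high_polyandry_g003_female4,female,female
high_polyandry_g004,high_polyandry,high_polyandry_g004_focal,male,focal
high_polyandry_g004,high_polyandry,high_polyandry_g004_rival1,male,rival
high_polyandry_g004,high_polyandry,high_polyandry_g004_rival2,male,rival
high_polyandry_g004,high_polyandry,high_polyandry_g004_rival3,male,rival
high_polyandry_g004,high_polyandry,high_polyandry_g004_female1,female,female
high_polyandry_g004,high_polyandry,high_polyandry_g004_female2,female,female
high_polyandry_g004,high_polyandry,high_polyandry_g004_female3,female,female
high_polyandry_g004,high_polyandry,high_polyandry_g004_female4,female,female
high_polyandry_g005,high_polyandry,high_polyandry_g005_focal,male,focal
high_polyandry_g005,high_polyandry,high_polyandry_g005_rival1,male,rival
high_polyandry_g005,high_polyandry,high_polyandry_g005_rival2,male,rival
high_polyandry_g005,high_polyandry,high_polyandry_g005_rival3,male,rival
high_polyandry_g005,high_polyandry,high_polyandry_g005_female1,female,female
high_polyandry_g005,high_polyandry,high_polyandry_g005_female2,female,female
high_polyandry_g005,high_polyandry,high_polyandry_g005_female3,female,female
high_polyandry_g005,high_polyandry,high_polyandry_g005_female4,female,female
high_polyandry_g006,high_polyandry,high_polyandry_g006_focal,male,focal
high_polyandry_g006,high_polyandry,high_polyandry_g006_rival1,male,rival
high_polyandry_g006,high_polyandry,high_polyandry_g006_rival2,male,rival
high_polyandry_g006,high_polyandry,high_polyandry_g006_rival3,male,rival
high_polyandry_g006,high_polyandry,high_polyandry_g006_female1,female,female
high_polyandry_g006,high_polyandry,high_polyandry_g006_female2,female,female
high_polyandry_g006,high_polyandry,high_polyandry_g006_female3,female,female
high_polyandry_g006,high_polyandry,high_polyandry_g006_female4,female,female
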