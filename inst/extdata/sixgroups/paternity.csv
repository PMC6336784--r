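group_id,female_id,daughters_focal,daughters_other
control_g001,control_g001_female1,15,30
control_g001,control_g001_female2,0,61
control_g001,control_g001_female3,21,29
control_g001,control_g001_female4,27,17
control_g002,control_g002_female1,33,18
control_g002,control_g002_female2,29,29
control_g002,control_g002_female3,0,43
control_g002,control_g002_female4,0,58
control_g003,control_g003_female1,0,45
control_g003,control_g003_female2,11,28
control_g003,control_g003_female3,0,52
control_g003,control_g003_female4,39,18
control_g004,control_g004_female1,0,48
control_g004,control_g004_female2,34,12
control_g004,control_g004_female3,0,59
control_g004,control_g004_female4,15,33
control_g005,control_g005_female1,0,42
control_g005,control_g005_female2,19,26
control_g005,control_g005_female3,0,45
control_g005,control_g005_female4,13,29
control_g006,control_g006_female1,0,41
control_g006,control_g006_female2,49,0
control_g006,control_g006_female3,40,0
control_g006,control_g006_female4,0,40
high_polyandry_g001,high_polyandry_g001_female1,20,17
high_polyandry_g001,high_polyandry_g001_female2,14,36
high_polyandry_g001,high_polyandry_g001_female3,7,34
high_polyandry_g001,high_polyandry_g001_female4,0,41
high_polyandry_g002,high_polyandry_g002_female1,9,24
high_polyandry_g002,high_polyandry_g002_female2,0,54
high_polyandry_g002,high_polyandry_g002_female3,0,50
high_polyandry_g002,high_polyandry_g002_female4,10,28
high_polyandry_g003,high_polyandry_g003_female1,14,31
high_polyandry_g003,high_polyandry_g003_female2,10,32
high_polyandry_g003,high_polyandry_g003_female3,21,15
high_polyandry_g003,high_polyandry_g003_female4,2,33
high_polyandry_g004,high_polyandry_g004_female1,4,20
high_polyandry_g004,high_polyandry_g004_female2,13,33
high_polyandry_g004,high_polyandry_g004_female3,16,25
high_polyandry_g004,high_polyandry_g004_female4,22,17
high_polyandry_g005,high_polyandry_g005_female1,18,20
high_polyandry_g005,high_polyandry_g005_female2,15,22
high_polyandry_g005,high_polyandry_g005_female3,21,19
high_polyandry_g005,high_polyandry_g005_female4,16,35
high_polyandry_g006,high_polyandry_g006_female1,14,28
high_polyandry_g006,high_polyandry_g006_female2,4,43
high_polyandry_g006,high_polyandry_g006_female3,9,28
high_polyandry_g006,high_polyandry_g006_female4,19,26
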