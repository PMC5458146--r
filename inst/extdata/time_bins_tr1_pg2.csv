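name,start_ma,end_ma
Tr1,251.9,241.8
Tr2,241.8,231.7
Tr3,231.7,221.6
Tr4,221.6,211.5
Tr5,211.5,201.4
J1,201.4,192.0
J2,192.0,182.6
J3,182.6,173.2
J4,173.2,163.8
J5,163.8,154.4
J6,154.4,145.0
K1,145.0,135.125
K2,135.125,125.25
K3,125.25,115.375
K4,115.375,105.5
K5,105.5,95.625
K6,95.625,85.75
K7,85.75,75.875
K8,75.875,66.0
Pg0,66.0,61.6
Pg1,61.6,56.0
Pg2,56.0,47.8
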