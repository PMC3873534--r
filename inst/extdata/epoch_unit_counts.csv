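patient_id,epoch_id,n_units
P01,e2,1
P01,e3,5
P02,e2,4
P02,e3,1
P03,e2,3
P03,e3,13
P04,e1,7
P04,e2,14
P04,e3,12
P05,e1,5
P05,e2,9
P05,e3,8
P06,e1,3
P06,e2,3
P07,e1,3
P07,e2,1
P08,e1,7
P08,e2,4
P08,e3,10
P09,e1,3
P09,e2,6
P09,e3,2
P10,e1,12
P10,e2,12
P10,e3,8
P11,e1,1
P11,e2,3
P11,e3,1
P12,e1,1
P12,e2,7
P12,e3,8
P13,e1,9
P13,e2,8
P13,e3,7
P14,e1,6
P14,e2,13
P14,e3,2
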