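sex,phase,chop_med,chop_q1,chop_q3,spoon_med,spoon_q1,spoon_q3
male,Re,4.9,2.4,9.6,2.9,1.8,3.5
male,Ta,1.0,0.7,2.2,1.0,0.7,1.4
male,Tr,0.8,0.6,1.4,0.9,0.7,1.2
male,Mo,0.4,0.3,0.5,0.7,0.6,0.8
female,Re,4.8,3.2,7.3,2.8,1.6,4.7
female,Ta,1.1,0.9,1.8,1.5,1.3,1.7
female,Tr,0.9,0.8,1.1,1.1,1.0,1.2
female,Mo,0.5,0.4,0.7,0.9,0.8,1.2
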