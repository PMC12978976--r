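sex,metric,chop_med,chop_q1,chop_q3,spoon_med,spoon_q1,spoon_q3
male,actual_distance_m,0.11,0.08,0.12,0.14,0.11,0.18
male,relative_distance,1.17,1.04,1.35,1.07,1.04,1.11
male,mean_velocity_mps,0.11,0.08,0.15,0.16,0.14,0.19
male,max_velocity_mps,0.18,0.16,0.28,0.25,0.22,0.32
male,timing_max_velocity_pct,70.6,61.7,83.2,60.2,45.1,75.8
male,n_movement_units,5.0,3.8,8.0,4.0,3.0,7.0
female,actual_distance_m,0.12,0.11,0.14,0.2,0.17,0.22
female,relative_distance,1.15,1.07,1.2,1.05,1.04,1.09
female,mean_velocity_mps,0.12,0.1,0.16,0.18,0.14,0.2
female,max_velocity_mps,0.22,0.19,0.29,0.35,0.28,0.37
female,timing_max_velocity_pct,70.3,63.4,75.9,63.9,56.4,69.2
female,n_movement_units,5.0,4.0,6.0,6.0,4.5,6.5
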