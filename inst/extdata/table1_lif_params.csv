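dataset,membrane_time_constant_ms,membrane_potential_threshold_mV,resting_potential_mV,voltage_reset_mV,current_pA,membrane_capacitance_pF
1,25.0,-43.0,-70.0,-70.0,200.0,170.21
2,22.0,-43.0,-70.0,-70.0,0.0,170.0
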