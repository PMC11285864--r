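name,b_peak_treat_mt,rise_fraction,rise_time_s,b_peak_control_mt,onset_ratio,notes
sota,101,0.5,0.0001,1,,double-wrapped solenoid; control mode leaks ~1 mT through incomplete field cancellation
mp09_2020,52,0.5,0.00117,5.2,1,270 uF bank with hard switch-off; sham is a truncation of the treatment pulse
custom_2021,52,0.5,0.00117,5.2,1,2x470 uF bank with flyback shut-off; sham is a truncation of the treatment pulse
indoor_0p5t,500,0.5,0.0005,0,,indoor-cage pulser; pulse shape unpublished (half peak within 0.5 ms assumed); no control pulse described
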