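task,measure,W,n,r_printed
in_out,mt_contrast,136,16,1
in_out,slr_gain_biceps,78,16,0.57
in_out,slr_gain_triceps,81,16,0.6
in_out,slr_gain_deltoid,76,16,0.56
in_out,slr_gain_pectoralis,83,16,0.61
in_out,slr_gain_brachioradialis,80,16,0.59
in_out,slr_latency,70.5,16,0.52
in_out,llr_mt_contrast,131,16,0.96
in_out,llr_gain_biceps,98,16,0.72
in_out,llr_gain_triceps,136,16,1
in_out,llr_gain_deltoid,135,16,0.99
in_out,llr_gain_pectoralis,96,16,0.71
in_out,llr_gain_brachioradialis,129,16,0.95
in_out,llr_latency,73,16,0.54
in_out,anticipatory_slr_noreward,83,16,0.61
in_out,anticipatory_slr_reward,88,16,0.65
in_out,anticipatory_llr_noreward,70,16,0.51
in_out,anticipatory_llr_reward,82,16,0.6
target_selection,mt_contrast,92,14,0.88
target_selection,gain_biceps,41,14,0.39
target_selection,gain_triceps,68,14,0.65
target_selection,gain_deltoid,54,14,0.51
target_selection,gain_pectoralis,59,14,0.56
target_selection,gain_brachioradialis,70,14,0.67
target_selection,latency,76,14,0.72
proprio_rt,mt_contrast,153,17,1
proprio_rt,rt_contrast,117.5,17,0.77
proprio_rt,gain_biceps,151,17,0.99
proprio_rt,gain_triceps,147,17,0.96
proprio_rt,gain_deltoid,152,17,0.99
proprio_rt,gain_pectoralis,123,17,0.8
proprio_rt,gain_brachioradialis,138,17,0.9
cursor_jump,mt_contrast,108,15,0.9
cursor_jump,gain_biceps,85,15,0.71
cursor_jump,gain_triceps,70,15,0.58
cursor_jump,gain_deltoid,76,15,0.63
cursor_jump,gain_pectoralis,73,15,0.61
cursor_jump,gain_brachioradialis,74,15,0.62
cursor_jump,latency,71,15,0.59
target_jump,mt_contrast,103,14,0.98
target_jump,gain_biceps,82,14,0.78
target_jump,gain_triceps,94,14,0.9
target_jump,gain_deltoid,74,14,0.7
target_jump,gain_pectoralis,105,14,1
target_jump,gain_brachioradialis,94,14,0.9
target_jump,latency,67,14,0.64
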