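# Target Jump task: mid-reach lateral jump of the goal target (or no jump).
task_id: target_jump
n_participants: 14
factors:
  jump: [inward, none, outward]
  reward: [rewarded, non_rewarded]
copies_per_combo: 2
epoch_size: 12
n_epochs: 26
n_blocks: 1
baseline_event: target_onset
mt_definition: exit_to_target_below_velocity
constants:
  fs_hz: 1000
  background_load_nm: 2.0
  perturbation_nm: 0.0
  onset_correction_ms: 0
contrasts:
  jump:
    a: {jump: inward}
    b: {jump: outward}
    width_ms: 50
    muscle: triceps_lat
    align_event: jump
    fit_start: window
return:
  form: movement_time
  g_max: 10
  conditions:
    - selector: {jump: inward}
      scaler: 0.999
      shifter: -0.026
      tau: 4.281
      mt_max: 2697
    - selector: {jump: none}
      scaler: 0.683
      shifter: -0.040
      tau: 3.893
      mt_max: 2882
    - selector: {jump: outward}
      scaler: 0.999
      shifter: -0.054
      tau: 3.853
      mt_max: 2690
geometry:
  target_distance_cm: 20
  target_radius_cm: 2
timing:
  pre_target_ms: 400
  hold_before_go_ms: [600, 700]
  post_entry_ms: 200
timing_notes: baseline window precedes target (go-cue) appearance; jumps occur mid-movement
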