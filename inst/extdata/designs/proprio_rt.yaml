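# Proprioception-cued Reaction Time task: small shoulder perturbation cues an
# elbow extension; reaction time read off the triceps EMG.
task_id: proprio_rt
n_participants: 17
factors:
  reward: [rewarded, non_rewarded]
copies_per_combo: 2
epoch_size: 4
n_epochs: 27
n_blocks: 1
baseline_event: perturbation
mt_definition: perturbation_to_target_entry
constants:
  fs_hz: 1000
  background_load_nm: 2.0
  perturbation_nm: 0.5
  onset_correction_ms: 4
contrasts:
  rt:
    a: {reward: rewarded}
    b: {reward: non_rewarded}
    width_ms: 50
    muscle: triceps_lat
    align_event: perturbation
    fit_start: event
return:
  form: movement_time
  g_max: 10
  conditions:
    - selector: {}
      scaler: 1.0
      shifter: 0.0
      tau: 2.447
      mt_max: 728
geometry:
  target_distance_cm: 12
  target_radius_cm: 3
timing:
  pre_target_ms: 400
  target_to_pert_ms: [600, 1000]
  post_pert_ms: 1000
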