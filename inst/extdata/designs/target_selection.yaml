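# Target Selection task: reach opposite the perturbation when two targets shown.
task_id: target_selection
n_participants: 14
factors:
  n_targets: [one, two]
  perturbation: [inward, outward]
  reward: [rewarded, non_rewarded]
copies_per_combo: 2
epoch_size: 16
n_epochs: 14
n_blocks: 2
baseline_event: perturbation
mt_definition: perturbation_to_target_entry
constants:
  fs_hz: 1000
  background_load_nm: 2.0
  perturbation_nm: 2.0
  onset_correction_ms: 4
contrasts:
  selection:
    a: {perturbation: inward, n_targets: two}
    b: {perturbation: inward, n_targets: one}
    width_ms: 50
    muscle: triceps_lat
    align_event: perturbation
    fit_start: event
return:
  form: movement_time
  g_max: 15
  conditions:
    - selector: {n_targets: one, perturbation: inward}
      scaler: 0.676
      shifter: -0.034
      tau: 6.236
      mt_max: 1673
    - selector: {n_targets: one, perturbation: outward}
      scaler: 0.690
      shifter: 0.004
      tau: 5.534
      mt_max: 2241
    - selector: {n_targets: two, perturbation: inward}
      scaler: 0.749
      shifter: -0.021
      tau: 4.904
      mt_max: 2373
    - selector: {n_targets: two, perturbation: outward}
      scaler: 0.749
      shifter: 0.009
      tau: 5.350
      mt_max: 2208
geometry:
  target_distance_cm: 14
  target_radius_cm: 7
timing:
  pre_target_ms: 400
  target_to_pert_ms: [600, 1000]
  post_pert_ms: 1400
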