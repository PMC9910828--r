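# In-Out Target task: elbow perturbations toward/away from an in/out target.
task_id: in_out
n_participants: 16
factors:
  perturbation: [inward, outward]
  target: [inward, outward]
  reward: [rewarded, non_rewarded]
copies_per_combo: 2
epoch_size: 16
n_epochs: 21
n_blocks: 3
baseline_event: perturbation
mt_definition: perturbation_to_target_entry
constants:
  fs_hz: 1000
  background_load_nm: 2.0
  perturbation_nm: 2.0
  onset_correction_ms: 4
contrasts:
  slr:
    a: {perturbation: inward}
    b: {perturbation: outward}
    width_ms: 25
    muscle: triceps_lat
    align_event: perturbation
    fit_start: event
  llr:
    a: {perturbation: inward, target: outward}
    b: {perturbation: inward, target: inward}
    width_ms: 50
    muscle: triceps_lat
    align_event: perturbation
    fit_start: event
return:
  form: time_in_target
  g_max: 15
  x0: 500
  xf: 800
  conditions:
    - selector: {perturbation: inward, target: outward}
      tau: 1.428
    - selector: {perturbation: outward, target: outward}
      tau: 2.600
    - selector: {perturbation: inward, target: inward}
      tau: 2.766
    - selector: {perturbation: outward, target: inward}
      tau: 1.351
geometry:
  target_distance_cm: 12
  target_radius_cm: 3
timing:
  pre_target_ms: 400
  target_to_pert_ms: [600, 600]
  post_pert_ms: 800
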