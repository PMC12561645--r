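# Versioned parameter registry: every (method, version) pair with its
# constants and unit tags. Acceleration thresholds are tagged in g unless the
# quantity is intrinsically on another scale. Parameters without a published
# value are package defaults and tagged accordingly in the `source` field.
registry_version: 1
gsd:
  hickey:
    wrist:
      thresholdstill: {value: 0.1, unit: g}
      thresholdupright: {value: 9.5, unit: g}
  kheirkhahan:
    wrist:
      threshold: {value: 0.58, unit: g}
      win_size: {value: 9, unit: epochs}
  maclean:
    wrist:
      threshold_binary: {value: 0.11, unit: g}
      gap_threshold: {value: 0.4, unit: s}
      gap_index: {value: 0.1, unit: fraction}
      walk_threshold: {value: 0.5, unit: s}
      walk_index: {value: 0.05, unit: fraction}
  keren:
    improved:
      threshold: {value: 0.08, unit: g}
      threshold_sd: {value: 0.07, unit: g}
      min_peaks: {value: 3, unit: count, source: default}
      regularity_floor: {value: 0.25, unit: corr, source: default}
      window_s: {value: 3, unit: s, source: default}
    adaptive:
      threshold_percentile: {value: 84, unit: percentile}
      threshold_sd: {value: 0.07, unit: g}
      min_peaks: {value: 3, unit: count, source: default}
      regularity_floor: {value: 0.25, unit: corr, source: default}
      window_s: {value: 3, unit: s, source: default}
  ionescu:
    wrist:
      active_signal_threshold: {value: 0.31, unit: g}
      lowpass_cutoff: {value: 3.0, unit: Hz, source: default}
    wrist_adaptive:
      active_signal_fallback_threshold: {value: 0.4, unit: g}
      percentile: {value: 31, unit: percentile}
      lowpass_cutoff: {value: 3.0, unit: Hz, source: default}
  iluz:
    wrist:
      std_threshold: {value: 0.06, unit: g}
      step_threshold: {value: 0.84, unit: corr}
icd:
  ducharme:
    wrist:
      threshold: {value: 0.01, unit: g}
  gu:
    improved:
      k: {value: 2, unit: count}
      period_min: {value: 25, unit: samples}
      period_max: {value: 120, unit: samples}
      sim_thres: {value: -0.7, unit: corr}
      var_thres: {value: 0.0005, unit: g2}
      mag_thres: {value: 1.1, unit: g}
    adaptive:
      k: {value: 2, unit: count}
      period_min: {value: 25, unit: samples}
      period_max: {value: 110, unit: samples}
      sim_thres: {value: -0.7, unit: corr}
      var_thres: {value: 0.4811805, unit: m_s2_2}
      mag_thres: {value: 70, unit: percentile}
  shin:
    original:
      window_s: {value: 0.05, unit: s, source: default}
      lag_s: {value: 0.25, unit: s, source: default}
  hklee:
    original:
      sgolay_window: {value: 21, unit: samples, source: default}
      sgolay_order: {value: 7, unit: count, source: default}
      gauss_window: {value: 10, unit: samples, source: default}
      gauss_sigma: {value: 2, unit: samples, source: default}
  zijlstra:
    wrist:
      cutoff: {value: 2.5, unit: Hz}
      peak_detection_method: {value: peak, unit: mode}
  micoamigo:
    wrist:
      peakdistance: {value: 1.1, unit: s}
      peakdistance_coef: {value: 1.0, unit: ratio}
      shiftfactor: {value: 0.15, unit: ratio}
      factorlimit: {value: 2, unit: ratio}
      event_offset: {value: 5, unit: samples}
  mccamley:
    wrist:
      cwt_method: {value: adaptive, unit: mode}
  pham:
    wrist:
      percentage_thresh: {value: 0.02, unit: ratio}
      cwt_method: {value: adaptive, unit: mode}
sl:
  weinberg:
    wrist:
      A: {value: 0.62, unit: gain}
      B: {value: 0, unit: m}
    wrist_footlength:
      A: {value: 0.21, unit: gain}
      B: {value: foot_length, unit: cm}
    wrist_adaptive:
      A: {value: 0.60, unit: gain}
      B: {value: 0, unit: m}
    wrist_adaptive_footlength:
      A: {value: 0.20, unit: gain}
      B: {value: foot_length, unit: cm}
  kim:
    wrist:
      A: {value: 0.35, unit: gain}
      B: {value: 0, unit: m}
    wrist_footlength:
      A: {value: 0.10, unit: gain}
      B: {value: foot_length, unit: cm}
    wrist_adaptive:
      A: {value: 0.35, unit: gain}
      B: {value: 0, unit: m}
    wrist_adaptive_footlength:
      A: {value: 0.10, unit: gain}
      B: {value: foot_length, unit: cm}
  bylemans:
    wrist:
      A: {value: 2.30, unit: gain}
      B: {value: 0, unit: m}
    wrist_footlength:
      A: {value: 0.75, unit: gain}
      B: {value: foot_length, unit: cm}
    wrist_adaptive:
      A: {value: 9.15, unit: gain}
      B: {value: 0, unit: m}
    wrist_adaptive_footlength:
      A: {value: 3.46, unit: gain}
      B: {value: foot_length, unit: cm}
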