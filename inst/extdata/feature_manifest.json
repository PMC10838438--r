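{
  "version": "1.0",
  "description": "Versioned manifest of the 53-feature acoustic set. Category counts: 5 jitter + 6 shimmer + 5 harmonicity + 7 F0 + 7 intensity + 2 ZCR + 21 timing/rate.",
  "features": [
    {"name": "jitter_local", "category": "jitter", "unit": "fraction"},
    {"name": "jitter_local_absolute", "category": "jitter", "unit": "s"},
    {"name": "jitter_rap", "category": "jitter", "unit": "fraction"},
    {"name": "jitter_ppq5", "category": "jitter", "unit": "fraction"},
    {"name": "jitter_ddp", "category": "jitter", "unit": "fraction"},
    {"name": "shimmer_local", "category": "shimmer", "unit": "fraction"},
    {"name": "shimmer_local_db", "category": "shimmer", "unit": "dB"},
    {"name": "shimmer_apq3", "category": "shimmer", "unit": "fraction"},
    {"name": "shimmer_apq5", "category": "shimmer", "unit": "fraction"},
    {"name": "shimmer_apq11", "category": "shimmer", "unit": "fraction"},
    {"name": "shimmer_dda", "category": "shimmer", "unit": "fraction"},
    {"name": "hnr_mean", "category": "harmonicity", "unit": "dB"},
    {"name": "hnr_sd", "category": "harmonicity", "unit": "dB"},
    {"name": "ac_mean", "category": "harmonicity", "unit": "correlation"},
    {"name": "cc_mean", "category": "harmonicity", "unit": "correlation"},
    {"name": "nhr_mean", "category": "harmonicity", "unit": "ratio"},
    {"name": "f0_mean", "category": "f0", "unit": "Hz"},
    {"name": "f0_median", "category": "f0", "unit": "Hz"},
    {"name": "f0_min", "category": "f0", "unit": "Hz"},
    {"name": "f0_max", "category": "f0", "unit": "Hz"},
    {"name": "f0_range", "category": "f0", "unit": "Hz"},
    {"name": "f0_var", "category": "f0", "unit": "Hz^2"},
    {"name": "f0_sd", "category": "f0", "unit": "Hz"},
    {"name": "int_mean", "category": "intensity", "unit": "dB"},
    {"name": "int_median", "category": "intensity", "unit": "dB"},
    {"name": "int_min", "category": "intensity", "unit": "dB"},
    {"name": "int_max", "category": "intensity", "unit": "dB"},
    {"name": "int_range", "category": "intensity", "unit": "dB"},
    {"name": "int_var", "category": "intensity", "unit": "dB^2"},
    {"name": "int_sd", "category": "intensity", "unit": "dB"},
    {"name": "zcr_mean", "category": "zcr", "unit": "fraction_per_sample"},
    {"name": "zcr_var", "category": "zcr", "unit": "fraction_per_sample^2"},
    {"name": "total_duration", "category": "timing_rate", "unit": "s"},
    {"name": "speech_time", "category": "timing_rate", "unit": "s"},
    {"name": "pause_time", "category": "timing_rate", "unit": "s"},
    {"name": "phonation_ratio", "category": "timing_rate", "unit": "fraction"},
    {"name": "pause_rate", "category": "timing_rate", "unit": "per_s"},
    {"name": "n_pauses", "category": "timing_rate", "unit": "count"},
    {"name": "n_pauses_short", "category": "timing_rate", "unit": "count"},
    {"name": "n_pauses_medium", "category": "timing_rate", "unit": "count"},
    {"name": "n_pauses_long", "category": "timing_rate", "unit": "count"},
    {"name": "pause_mean_dur", "category": "timing_rate", "unit": "s"},
    {"name": "pause_var_dur", "category": "timing_rate", "unit": "s^2"},
    {"name": "pause_max_dur", "category": "timing_rate", "unit": "s"},
    {"name": "n_speech_segments", "category": "timing_rate", "unit": "count"},
    {"name": "speech_seg_mean_dur", "category": "timing_rate", "unit": "s"},
    {"name": "speech_seg_var_dur", "category": "timing_rate", "unit": "s^2"},
    {"name": "speech_seg_max_dur", "category": "timing_rate", "unit": "s"},
    {"name": "speech_rate", "category": "timing_rate", "unit": "syllables_per_s"},
    {"name": "articulation_rate", "category": "timing_rate", "unit": "syllables_per_s"},
    {"name": "syllable_count", "category": "timing_rate", "unit": "count"},
    {"name": "word_dur_mean", "category": "timing_rate", "unit": "s"},
    {"name": "word_dur_var", "category": "timing_rate", "unit": "s^2"}
  ]
}
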