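# Example analysis configuration for follower-tools / readAnalysisConfig().
# Windows in seconds; n_iter is the number of circular shuffles.
window_response: 0.4
window_baseline: 0.6
n_iter: 5000
exclusion: 1.0
threshold_mode: default
threshold_upper: 2.1
threshold_lower: -2.3
n_trials: 190
frame_rate: 10
seed: 1
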