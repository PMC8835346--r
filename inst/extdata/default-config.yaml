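# Default pipeline settings: 5 dummy volumes discarded, 0.01-0.08 Hz
# band, 0.2 mm FD scrubbing, 12-TR Hamming window stepped by 1 TR
# (28.8 s at TR 2.4 s), k selected by the elbow criterion over 2-20
# (the pipeline_config default) with 500 exemplar-stage
# k-means restarts.
n_discard: 5
low_hz: 0.01
high_hz: 0.08
fd_threshold_mm: 0.2
window_width_tr: 12
window_step_tr: 1
taper: hamming
tr_seconds: 2.4
kmeans_restarts: 500
elbow_restarts: 50
design: between
seed: 1
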