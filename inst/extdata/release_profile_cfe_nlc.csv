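time_h,cumulative_release_pct
2,19.74
3,22.58
24,61.12
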