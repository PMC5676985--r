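metric,unfiltered,filtered
tie_points,58193,110089
projections,272078,445291
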