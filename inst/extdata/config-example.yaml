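# Example configuration overrides. Entries omitted here keep the
# package defaults (per-source evidence scores, DScore lookup, per-kind
# thresholds).
alpha: 0.01
min_group_size: 5
s_min: 10
alias_policy: error
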