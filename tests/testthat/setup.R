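# Computed once per test run: the bundled model, its full fixed-point set
# and the classified profile table under the default configuration.
bundled_model <- macrophage_model()
bundled_fp <- enumerate_all_fixed_points(bundled_model$network)
bundled_table <- classify_profiles(
  project_and_dedup(bundled_fp, drop_nodes = bundled_model$network$inputs),
  bundled_model$signatures, "priority"
)
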