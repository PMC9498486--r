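# end-to-end run on the synthetic example data shipped with the package.
# Paths are relative to the working directory; replace with absolute paths
# (e.g. from system.file("extdata", ..., package = "tscmr")) as needed.
exposure_path: synthetic_exposure.tsv
outcome_path: synthetic_outcome.tsv
confounder_paths:
  metabolic: synthetic_confounder.tsv
instruments: [rs1001, rs1002, rs1003]
p_threshold: 5.0e-8
confounder_p_threshold: 5.0e-8
q_pvalue_threshold: 0.05
palindrome_eaf_window: 0.08
n_boot: 10000
seed: 1
out_dir: tscmr_output
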