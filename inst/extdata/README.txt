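table2_printed.tsv   Published Mendelian-randomization summary table
                     (rounded, as printed: beta, 95%/90% CIs, p) used for
                     interval-arithmetic consistency checks. The ci_check
                     column flags rows whose printed intervals are mutually
                     consistent under the normal approximation; the
                     "47 SNPs" row's printed 95% lower bound is not and is
                     excluded by design.
synthetic_cohort_*   Small synthetic demonstration cohort generated by
                     grsmr::simulate_cohort() (seed 42): dosage TSV (+ .meta
                     variant sidecar), phenotype CSV and external-style
                     weight table. Synthetic data; no real subjects.
config_example.yaml  Self-contained pipeline configuration (simulation
                     block) for run_pipeline() and the inst/cli/grsmr
                     driver.
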