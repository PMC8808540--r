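## Shared simulated studies, generated once per test session.

.study_env <- new.env(parent = emptyenv())

## desk-scale study small enough for per-module tests: one 1.2-Mb
## chromosome, 4 cell types x 2 conditions x 2 replicates, 40k reads
small_sim_params <- function(...) {
  sim_params(n_chroms = 1, chrom_length = 1.2e6, n_genes = 40,
             n_shared = 40, n_celltype = 12, n_differential = 8,
             n_exclusive = 8, n_reads_chip = 4e4, n_reads_input = 4e4,
             n_replicates = 2, n_snps = 24, snp_frac_proximal = 0.5,
             n_housekeeping = 12, n_ct_genes = 4, n_blacklist = 2, ...)
}

## the small study carries one deliberately shallow extra technical
## replicate (depth/20) so the peak-count QC gate is exercised
get_small_study <- function() {
  if (is.null(.study_env$small)) {
    dir <- file.path(tempdir(), "chipscape_small_study")
    extra <- data.frame(sample_id = "BC_NC_rep1_t2", cell_type = "BC",
                        condition = "NC", mark = "H3K27ac", replicate = 1,
                        tech_rep = 2, role = "chip", depth_factor = 1 / 20)
    .study_env$small <- simulate_study(small_sim_params(), dir,
                                       extra_samples = extra)
  }
  .study_env$small
}

get_small_report <- function() {
  if (is.null(.study_env$small_report)) {
    st <- get_small_study()
    cfg <- synthetic_config(st$dir, file.path(tempdir(), "chipscape_small_out"),
                            min_peaks = 50, snp_window = 2000, seed = 1)
    .study_env$small_report <- run_pipeline(cfg)
  }
  .study_env$small_report
}

## the full default study (reference conditions) used by the recovery
## and structure acceptance checks
get_default_study <- function() {
  if (is.null(.study_env$full)) {
    dir <- file.path(tempdir(), "chipscape_full_study")
    .study_env$full <- simulate_study(sim_params(), dir)
  }
  .study_env$full
}

get_default_report <- function() {
  if (is.null(.study_env$full_report)) {
    st <- get_default_study()
    cfg <- synthetic_config(st$dir, file.path(tempdir(), "chipscape_full_out"),
                            seed = 1)
    .study_env$full_report <- run_pipeline(cfg)
  }
  .study_env$full_report
}
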