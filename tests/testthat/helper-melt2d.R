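# shared fixtures built in code

the_panel <- load_panel(melt2d_panel_file())

# calibrated (channel, Tm) coordinates of the nine-locus panel
calibrated_coords <- tibble::tribble(
  ~locus_id,        ~allele,  ~channel,   ~tm_c,
  "c.919-2A>G",     "wild",   "FAM",      66.8,
  "c.919-2A>G",     "mutant", "HEX",      67.2,
  "c.235delC",      "wild",   "FAM",      64.4,
  "c.235delC",      "mutant", "HEX",      63.2,
  "c.176-191del16", "wild",   "FAM",      59.6,
  "c.176-191del16", "mutant", "HEX",      59.6,
  "c.299_300delAT", "wild",   "FAM",      53.2,
  "c.299_300delAT", "mutant", "HEX",      56.4,
  "c.1229C>T",      "wild",   "FAM",      48.4,
  "c.1229C>T",      "mutant", "Alexa568", 66.0,
  "c.2168A>G",      "wild",   "FAM",      41.2,
  "c.2168A>G",      "mutant", "Alexa568", 62.0,
  "c.538C>T",       "wild",   "FAM",      36.4,
  "c.538C>T",       "mutant", "Alexa568", 50.4,
  "m.1494C>T",      "wild",   "HEX",      47.2,
  "m.1494C>T",      "mutant", "Alexa568", 41.6,
  "m.1555A>G",      "wild",   "HEX",      42.4,
  "m.1555A>G",      "mutant", "Alexa568", 35.6)

# mutant-allele frequencies of the study cohort (per-locus, fractional)
study_freqs <- c("c.235delC" = 0.159, "c.299_300delAT" = 0.060,
                 "c.176-191del16" = 0.026, "c.919-2A>G" = 0.073,
                 "c.2168A>G" = 0.022, "m.1555A>G" = 0.017)

# genotype table with one non-wild class at a single locus
single_locus_genotype <- function(locus_id, genotype,
                                  panel = the_panel) {
  gt <- all_wild_genotype(panel)
  gt$genotype[gt$locus_id == locus_id] <- genotype
  gt
}

# decode a simulated trace table with pipeline defaults
roundtrip_calls <- function(genotype, noise_sd = 0, seed = NULL,
                            panel = the_panel) {
  tr <- simulate_sample(panel, genotype, sample_id = "rt",
                        noise_sd = noise_sd, seed = seed)
  call_cohort(panel, tr)
}

# QC flags that indicate a decoding problem (heteroplasmy is a valid,
# merely unexpected, call and is excluded)
problem_flags <- function(qc) {
  grepl("unassigned|no_call|conflict|competing|hex_split", qc)
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_script <- function() {
  system.file("cli", "melt2d.R", package = "melt2d", mustWork = TRUE)
}

run_cli <- function(args, ...) {
  res <- suppressWarnings(
    system2(rscript_bin(), c(cli_script(), args),
            stdout = TRUE, stderr = TRUE, ...))
  list(status = attr(res, "status") %||% 0L, output = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
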