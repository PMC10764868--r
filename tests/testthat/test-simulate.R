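# independent peak locator: raw finite differences on the rendered trace,
# no smoothing, no package peak caller
raw_deriv_argmax <- function(trace) {
  d <- -diff(trace$fluorescence) / diff(trace$temperature)
  mid <- (trace$temperature[-1] + trace$temperature[-nrow(trace)]) / 2
  mid[which.max(d)]
}

raw_local_maxima <- function(trace, min_height = 0.05) {
  d <- -diff(trace$fluorescence) / diff(trace$temperature)
  mid <- (trace$temperature[-1] + trace$temperature[-nrow(trace)]) / 2
  n <- length(d)
  idx <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  mid[idx[d[idx] >= min_height]]
}

test_that("a single rendered component melts at its Tm", {
  tr <- render_channel(data.frame(tm = 64.4, amplitude = 1, width = 0.5),
                       channel = "FAM", sample_id = "s")
  expect_equal(raw_deriv_argmax(tr), 64.4, tolerance = 0.11)
  # monotone non-increasing overall (pure melt, no baseline)
  expect_true(all(diff(tr$fluorescence) <= 1e-12))
})

test_that("empty component list with no baseline or noise is flat zero", {
  tr <- render_channel(data.frame(tm = numeric(0), amplitude = numeric(0),
                                  width = numeric(0)),
                       channel = "FAM", sample_id = "s")
  expect_true(all(tr$fluorescence == 0))
  expect_equal(nrow(tr), length(melt_grid()))
})

test_that("two components 2.4 degrees apart are resolvable", {
  tr <- render_channel(data.frame(tm = c(66.8, 64.4), amplitude = c(1, 1),
                                  width = 0.5),
                       channel = "FAM", sample_id = "s")
  peaks <- raw_local_maxima(tr)
  expect_length(peaks, 2L)
  expect_equal(sort(peaks), c(64.4, 66.8), tolerance = 0.01)
})

test_that("rendering validates its inputs", {
  expect_error(render_channel(data.frame(tm = 50, amplitude = 1, width = 0.5),
                              grid = c(30, 30, 31)), "increasing")
  expect_error(render_channel(data.frame(tm = 50, amplitude = -1, width = 0.5)),
               "amplitude")
  expect_error(render_channel(data.frame(tm = 50, amplitude = 1, width = 0.5),
                              noise_sd = -1), "noise_sd")
})

test_that("genotype dosage maps to component amplitude and channel", {
  # heterozygote: 0.5 wild + 0.5 mutant at the locus coordinates
  gt <- single_locus_genotype("c.235delC", "WM")
  comps <- sample_components(the_panel, gt)
  fam <- comps[comps$channel == "FAM", ]
  hex <- comps[comps$channel == "HEX", ]
  expect_equal(fam$amplitude[fam$tm == 64.4], 0.5)
  # HEX carries the 0.5-dose mutant component plus the wild mito peaks
  expect_setequal(hex$tm, c(63.2, 47.2, 42.4))
  expect_equal(hex$amplitude[hex$tm == 63.2], 0.5)
  expect_true(all(hex$amplitude[hex$tm != 63.2] == 1))

  # all-wild: no Alexa568 components; 7 FAM + 2 HEX (mito wild) peaks
  comps <- sample_components(the_panel, all_wild_genotype(the_panel))
  expect_equal(sum(comps$channel == "Alexa568"), 0L)
  expect_setequal(comps$tm[comps$channel == "FAM"],
                  c(66.8, 64.4, 59.6, 53.2, 48.4, 41.2, 36.4))
  expect_setequal(comps$tm[comps$channel == "HEX"], c(47.2, 42.4))
  expect_true(all(comps$amplitude == 1))

  # all-mutant: no FAM components; 4 HEX + 5 Alexa568
  gt <- all_wild_genotype(the_panel)
  gt$genotype <- ifelse(gt$genotype == "WW", "MM", "mutant_homoplasmic")
  comps <- sample_components(the_panel, gt)
  expect_equal(sum(comps$channel == "FAM"), 0L)
  expect_setequal(comps$tm[comps$channel == "HEX"],
                  c(67.2, 63.2, 59.6, 56.4))
  expect_setequal(comps$tm[comps$channel == "Alexa568"],
                  c(66.0, 62.0, 50.4, 41.6, 35.6))

  # per-channel component count equals distinct present alleles
  gt <- single_locus_genotype("m.1494C>T", "heteroplasmic")
  comps <- sample_components(the_panel, gt)
  expect_equal(sum(comps$channel == "HEX"), 2L)      # 47.2 (het) + 42.4
  expect_equal(sum(comps$channel == "Alexa568"), 1L) # 41.6 (het)

  expect_error(sample_components(the_panel,
                                 data.frame(locus_id = "c.235delC",
                                            genotype = "WM")),
               "missing panel locus")
  expect_error(
    sample_components(the_panel,
                      single_locus_genotype("m.1555A>G", "WM")),
    "invalid for mitochondrial")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  gt <- all_wild_genotype(the_panel)
  a <- simulate_sample(the_panel, gt, sample_id = "s", seed = 11)
  b <- simulate_sample(the_panel, gt, sample_id = "s", seed = 11)
  expect_identical(a, b)
  c <- simulate_sample(the_panel, gt, sample_id = "s", seed = 12)
  expect_false(identical(a$fluorescence, c$fluorescence))
})

test_that("fixture cohort replays the published genotype composition", {
  coh <- fixture_cohort(the_panel)
  ids <- unique(coh$sample_id)
  expect_length(ids, 116L)
  expect_equal(nrow(coh), 116L * 9L)
  expect_equal(attr(coh, "provenance"), "fixture")

  per_sample_mut <- tapply(
    coh$genotype %in% c("WM", "MM", "mutant_homoplasmic", "heteroplasmic"),
    coh$sample_id, any)
  expect_equal(sum(per_sample_mut), 50L)
  expect_equal(sum(!per_sample_mut), 66L)

  n_gt <- function(locus, gt) sum(coh$locus_id == locus & coh$genotype == gt)
  expect_equal(n_gt("c.235delC", "MM"), 10L)
  expect_equal(n_gt("c.235delC", "WM"), 17L)
  expect_equal(n_gt("c.176-191del16", "MM"), 1L)
  expect_equal(n_gt("c.299_300delAT", "MM"), 2L)
  expect_equal(n_gt("c.919-2A>G", "MM"), 3L)
  expect_equal(n_gt("c.919-2A>G", "WM"), 11L)
  expect_equal(n_gt("c.2168A>G", "WM"), 5L)
  expect_equal(n_gt("m.1555A>G", "mutant_homoplasmic"), 2L)
  expect_equal(n_gt("m.1494C>T", "mutant_homoplasmic"), 0L)
  expect_equal(n_gt("c.1229C>T", "WM") + n_gt("c.1229C>T", "MM"), 0L)
  expect_equal(n_gt("c.538C>T", "WM") + n_gt("c.538C>T", "MM"), 0L)

  # one m.1555A>G carrier also carries the SLC26A4 compound heterozygote
  mt_ids <- coh$sample_id[coh$locus_id == "m.1555A>G" &
                            coh$genotype == "mutant_homoplasmic"]
  s4 <- coh[coh$sample_id %in% mt_ids &
              coh$locus_id %in% c("c.919-2A>G", "c.2168A>G"), ]
  both_het <- tapply(s4$genotype == "WM", s4$sample_id, all)
  expect_equal(sum(both_het), 1L)
})

test_that("random cohorts follow the requested allele frequencies", {
  coh <- sample_cohort(the_panel, 10, seed = 5)  # all frequencies zero
  expect_true(all(coh$genotype %in% c("WW", "wild_homoplasmic")))

  coh <- sample_cohort(the_panel, 10, c("c.235delC" = 1), seed = 5)
  expect_true(all(coh$genotype[coh$locus_id == "c.235delC"] == "MM"))

  n <- 10000
  f <- 0.159
  coh <- sample_cohort(the_panel, n, c("c.235delC" = f), seed = 99)
  g <- coh$genotype[coh$locus_id == "c.235delC"]
  observed <- (sum(g == "WM") + 2 * sum(g == "MM")) / (2 * n)
  se <- sqrt(f * (1 - f) / (2 * n))
  expect_lt(abs(observed - f), 3 * se)

  expect_identical(sample_cohort(the_panel, 50, study_freqs, seed = 3),
                   sample_cohort(the_panel, 50, study_freqs, seed = 3))
  expect_error(sample_cohort(the_panel, 5, c("c.235delC" = 1.2)), "\\[0, 1\\]")
  expect_error(sample_cohort(the_panel, 5, c(nope = 0.1)), "unknown locus")
})
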