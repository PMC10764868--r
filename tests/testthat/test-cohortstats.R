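test_that("fixture cohort summary reproduces the study tables", {
  s <- summarize_cohort(fixture_cohort(the_panel), the_panel)
  expect_equal(s$n_samples, 116L)

  pos <- s$gene_positivity
  expect_equal(pos$n_positive[pos$gene == "GJB2"], 34L)
  expect_equal(pos$pct[pos$gene == "GJB2"], 29.3)
  expect_equal(pos$n_positive[pos$gene == "SLC26A4"], 15L)
  expect_equal(pos$pct[pos$gene == "SLC26A4"], 12.9)
  expect_equal(pos$n_positive[pos$gene == "MT-RNR1"], 2L)
  expect_equal(pos$pct[pos$gene == "MT-RNR1"], 1.7)

  cat_n <- function(gene, category) {
    gc <- s$gene_categories
    gc$n[gc$gene == gene & gc$category == category]
  }
  expect_equal(cat_n("GJB2", "homozygous"), 13L)
  expect_equal(cat_n("GJB2", "compound heterozygous"), 10L)
  expect_equal(cat_n("GJB2", "heterozygous"), 11L)
  expect_equal(cat_n("SLC26A4", "homozygous"), 3L)
  expect_equal(cat_n("SLC26A4", "compound heterozygous"), 4L)
  expect_equal(cat_n("SLC26A4", "heterozygous"), 8L)
  expect_equal(cat_n("MT-RNR1", "homoplasmic"), 2L)

  sf <- s$site_frequencies
  row <- function(loc) sf[sf$locus_id == loc, ]
  expect_equal(row("c.235delC")$het, 17L)
  expect_equal(row("c.235delC")$hom, 10L)
  expect_equal(row("c.235delC")$freq_pct, 15.9)
  expect_equal(row("c.299_300delAT")$freq_pct, 6.0)
  expect_equal(row("c.176-191del16")$freq_pct, 2.6)
  expect_equal(row("c.919-2A>G")$freq_pct, 7.3)
  expect_equal(row("c.2168A>G")$freq_pct, 2.2)
  expect_equal(row("m.1555A>G")$freq_pct, 1.7)
  expect_equal(row("m.1555A>G")$denominator, 116L)
  expect_true(all(sf$denominator[sf$gene != "MT-RNR1"] == 232L))

  expect_equal(s$overall$n_carriers, 50L)
  expect_equal(s$overall$pct, 43.1)
})

test_that("empty cohorts and unknown loci are handled explicitly", {
  empty <- fixture_cohort(the_panel)[0, ]
  s <- summarize_cohort(empty, the_panel)
  expect_equal(s$n_samples, 0L)
  expect_equal(s$overall$n_carriers, 0L)
  expect_true(all(is.na(s$site_frequencies$freq_pct)))

  bad <- fixture_cohort(the_panel)
  bad$locus_id[1] <- "c.42A>T"
  expect_error(summarize_cohort(bad, the_panel), "unknown locus")

  nc <- fixture_cohort(the_panel)
  nc$genotype[5] <- "no_call"
  expect_error(summarize_cohort(nc, the_panel), "no_call")
})

test_that("allele bookkeeping is internally consistent on random cohorts", {
  for (seed in 1:3) {
    coh <- sample_cohort(the_panel, 80, study_freqs, seed = seed)
    s <- summarize_cohort(coh, the_panel)
    sf <- s$site_frequencies
    # per-site alleles recomputed independently from the genotype table
    for (i in seq_len(nrow(sf))) {
      g <- coh$genotype[coh$locus_id == sf$locus_id[i]]
      expected <- if (sf$gene[i] == "MT-RNR1") {
        sum(g %in% c("mutant_homoplasmic", "heteroplasmic"))
      } else {
        sum(g == "WM") + 2L * sum(g == "MM")
      }
      expect_equal(sf$mutant_alleles[i], expected)
      # wild + mutant frequencies are complementary
      expect_equal(sf$mutant_alleles[i] / sf$denominator[i] +
                     (sf$denominator[i] - sf$mutant_alleles[i]) /
                     sf$denominator[i], 1)
    }
  }

  # the fixture's category bookkeeping: gene alleles split over categories
  s <- summarize_cohort(fixture_cohort(the_panel), the_panel)
  gjb2 <- s$site_frequencies[s$site_frequencies$gene == "GJB2", ]
  gc <- s$gene_categories
  n_of <- function(cat) gc$n[gc$gene == "GJB2" & gc$category == cat]
  expect_equal(sum(gjb2$mutant_alleles),
               2L * n_of("homozygous") + 2L * n_of("compound heterozygous") +
                 n_of("heterozygous"))
})

test_that("pearson chi-square matches the textbook formula and chisq.test", {
  res <- chi_square_2x2(37, 195, 721, 5287)
  expect_equal(round(res$statistic, 2), 3.26)
  expect_equal(res$df, 1L)

  # equal proportions give zero
  expect_equal(chi_square_2x2(10, 90, 20, 180)$statistic, 0)
  # transposition symmetry
  expect_equal(chi_square_2x2(37, 195, 721, 5287)$statistic,
               chi_square_2x2(37, 721, 195, 5287)$statistic)

  set.seed(404)
  for (i in 1:1000) {
    x <- rpois(4, lambda = sample(c(5, 50, 500), 1)) + 1L
    mine <- chi_square_2x2(x[1], x[2], x[3], x[4])
    ref <- suppressWarnings(
      chisq.test(matrix(x, 2, byrow = TRUE), correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }

  expect_error(chi_square_2x2(0, 0, 5, 5), "margins")
  expect_error(chi_square_2x2(1.5, 2, 3, 4), "integers")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("regional comparison reconstructs external counts from rates", {
  cmp <- compare_with_region(37, 232, 12.0, 3004, basis = "allele",
                             site = "c.235delC")
  expect_equal(cmp$external_n, 6008L)
  expect_equal(cmp$external_k, 721)
  expect_equal(round(cmp$chi_square, 2), 3.26)
  expect_gt(cmp$p_value, 0.05)

  # equal rates give a near-zero statistic
  cmp <- compare_with_region(116, 232, 50, 3004, basis = "allele")
  expect_lt(cmp$chi_square, 0.01)

  # carrier basis does not double the external denominator
  cmp <- compare_with_region(27, 116, 16.3, 3004, basis = "carrier")
  expect_equal(cmp$external_n, 3004L)
  expect_true(cmp$chi_square >= 3.9 && cmp$chi_square <= 4.1)
  expect_lt(cmp$p_value, 0.05)

  expect_error(compare_with_region(5, 10, 120, 100), "\\[0, 100\\]")
  expect_error(compare_with_region(5, 10, 12, 0), "positive")
})

test_that("cohen's kappa behaves across agreement regimes", {
  coh <- fixture_cohort(the_panel)
  k <- cohens_kappa(coh, coh)
  expect_equal(k$kappa, 1)
  expect_equal(k$po, 1)
  expect_lt(k$p_value, 0.001)

  # zero agreement on a two-category toy set is at or below chance
  a <- tibble::tibble(sample_id = sprintf("s%02d", 1:20), locus_id = "l",
                      genotype = rep(c("WW", "WM"), 10))
  b <- a
  b$genotype <- ifelse(a$genotype == "WW", "WM", "WW")
  expect_lte(cohens_kappa(a, b)$kappa, 0)

  # 90% agreement, symmetric 45/5/5/45 confusion: kappa = 0.8
  a <- tibble::tibble(sample_id = sprintf("s%03d", 1:100), locus_id = "l",
                      genotype = rep(c("WW", "WM"), each = 50))
  b <- a
  b$genotype[1:5] <- "WM"
  b$genotype[51:55] <- "WW"
  expect_equal(cohens_kappa(a, b)$kappa, 0.8)

  # invariant to category relabeling and to row order
  relab <- function(x) {
    x$genotype <- c(WW = "x", WM = "y")[x$genotype]
    x
  }
  expect_equal(cohens_kappa(relab(a), relab(b))$kappa,
               cohens_kappa(a, b)$kappa)
  shuffle <- sample(nrow(a))
  expect_equal(cohens_kappa(a[shuffle, ], b)$kappa,
               cohens_kappa(a, b)$kappa)

  # degenerate single-category total agreement is defined as 1
  one <- tibble::tibble(sample_id = "s1", locus_id = c("l1", "l2"),
                        genotype = "WW")
  expect_equal(cohens_kappa(one, one)$kappa, 1)

  bad <- a
  bad$sample_id[1] <- "other"
  expect_error(cohens_kappa(a, bad), "different")
})
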