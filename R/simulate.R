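#' Default fluorescence acquisition grid
#'
#' The instrument protocol ramps from 30 to 70 degrees C while acquiring
#' continuously; the software contract is a fixed uniform grid over that
#' window.
#'
#' @param from,to,step grid limits and spacing in degrees C.
#' @return Numeric vector of temperatures.
#' @export
melt_grid <- function(from = 30, to = 70, step = 0.1) {
  seq(from, to, by = step)
}

#' Render one channel's melting trace from duplex components
#'
#' Each probe--tag duplex contributes a two-state melting transition:
#' fluorescence `amplitude * plogis((tm - T) / width)`, i.e. a sigmoid
#' that is high below its Tm and melts away above it, whose negative
#' derivative peaks exactly at `tm`.  Components are summed and a linear
#' baseline plus additive Gaussian noise are overlaid.
#'
#' @param components data frame with columns `tm`, `amplitude`, `width`
#'   (may have zero rows).
#' @param grid ascending temperature grid (degrees C).
#' @param baseline_slope,baseline_intercept linear baseline, expressed in
#'   fluorescence units per degree C relative to the grid start.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed optional integer seed (sets the RNG).
#' @param channel,sample_id identifiers copied into the output.
#' @return Tibble with columns `sample_id`, `channel`, `temperature`,
#'   `fluorescence`.
#' @examples
#' tr <- render_channel(data.frame(tm = 64.4, amplitude = 1, width = 0.5),
#'                      channel = "FAM", sample_id = "s1")
#' @export
render_channel <- function(components, grid = melt_grid(),
                           baseline_slope = 0, baseline_intercept = 0,
                           noise_sd = 0, seed = NULL,
                           channel = NA_character_,
                           sample_id = NA_character_) {
  if (any(diff(grid) <= 0)) {
    stop("temperature grid must be strictly increasing", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  components <- as.data.frame(components)
  f <- rep(0, length(grid))
  if (nrow(components) > 0L) {
    if (any(components$amplitude <= 0) || any(components$width <= 0)) {
      stop("component amplitude and width must be > 0", call. = FALSE)
    }
    for (i in seq_len(nrow(components))) {
      f <- f + components$amplitude[i] *
        plogis((components$tm[i] - grid) / components$width[i])
    }
  }
  f <- f + baseline_intercept + baseline_slope * (grid - grid[1])
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) f <- f + rnorm(length(grid), sd = noise_sd)
  tibble(sample_id = sample_id, channel = channel,
         temperature = grid, fluorescence = f)
}

# dosage of each allele implied by a genotype class
allele_dosage <- function(genotype) {
  switch(genotype,
         WW = c(wild = 1),
         WM = c(wild = 0.5, mutant = 0.5),
         MM = c(mutant = 1),
         wild_homoplasmic = c(wild = 1),
         mutant_homoplasmic = c(mutant = 1),
         heteroplasmic = c(wild = 0.5, mutant = 0.5),
         stop(sprintf("unknown genotype class '%s'", genotype),
              call. = FALSE))
}

#' Duplex components implied by a sample genotype
#'
#' Every allele present in the genotype contributes one component at its
#' calibrated (channel, Tm) coordinate.  Heterozygous / heteroplasmic
#' alleles get amplitude 0.5 each, homozygous / homoplasmic alleles 1.0;
#' per-channel scale factors can emulate unequal probe amounts.
#'
#' @param panel a [melt_panel].
#' @param genotype data frame with columns `locus_id`, `genotype`
#'   covering every panel locus exactly once (diploid classes `WW`, `WM`,
#'   `MM`; mitochondrial `wild_homoplasmic`, `mutant_homoplasmic`,
#'   `heteroplasmic`).
#' @param width transition width in degrees C.
#' @param channel_scale named amplitude multipliers per channel.
#' @return Tibble with columns `channel`, `tm`, `amplitude`, `width`.
#' @export
sample_components <- function(panel, genotype, width = 0.5,
                              channel_scale = c(FAM = 1, HEX = 1,
                                                Alexa568 = 1)) {
  stopifnot(inherits(panel, "melt_panel"))
  genotype <- as.data.frame(genotype)
  miss <- setdiff(panel$loci$locus_id, genotype$locus_id)
  if (length(miss) > 0L) {
    stop(sprintf("genotype missing panel locus: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(genotype$locus_id)) {
    stop("duplicate locus in genotype", call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(genotype))) {
    loc <- genotype$locus_id[i]
    if (!loc %in% panel$loci$locus_id) {
      stop(sprintf("unknown locus '%s'", loc), call. = FALSE)
    }
    gt <- genotype$genotype[i]
    ploidy <- panel_ploidy(panel, loc)
    ok <- if (ploidy == "diploid") DIPLOID_CLASSES else MITO_CLASSES
    if (!gt %in% ok) {
      stop(sprintf("genotype class '%s' invalid for %s locus %s",
                   gt, ploidy, loc), call. = FALSE)
    }
    dose <- allele_dosage(gt)
    for (allele in names(dose)) {
      co <- panel_coordinate(panel, loc, allele)
      out[[length(out) + 1L]] <- tibble(
        channel = co$channel, tm = co$tm_c,
        amplitude = dose[[allele]] * channel_scale[[co$channel]],
        width = width)
    }
  }
  bind_rows(out)
}

#' Simulate the three-channel melting trace of one sample
#'
#' @inheritParams sample_components
#' @param sample_id sample identifier.
#' @param grid temperature grid.
#' @param noise_sd Gaussian noise standard deviation (relative to unit
#'   amplitude); default 0.005.
#' @param baseline_slope linear baseline slope in units per degree C;
#'   default -0.002.
#' @param seed optional integer seed; with a fixed seed the output is
#'   bit-reproducible.
#' @return Long tibble of three melting traces (`sample_id`, `channel`,
#'   `temperature`, `fluorescence`), one block per channel.
#' @examples
#' panel <- load_panel(melt2d_panel_file())
#' gt <- all_wild_genotype(panel)
#' tr <- simulate_sample(panel, gt, sample_id = "s1", seed = 1)
#' @export
simulate_sample <- function(panel, genotype, sample_id = "sample",
                            grid = melt_grid(), noise_sd = 0.005,
                            baseline_slope = -0.002, width = 0.5,
                            channel_scale = c(FAM = 1, HEX = 1,
                                              Alexa568 = 1),
                            seed = NULL) {
  comps <- sample_components(panel, genotype, width = width,
                             channel_scale = channel_scale)
  if (!is.null(seed)) set.seed(seed)
  bind_rows(lapply(MELT_CHANNELS, function(ch) {
    render_channel(comps[comps$channel == ch, c("tm", "amplitude", "width")],
                   grid = grid, baseline_slope = baseline_slope,
                   noise_sd = noise_sd, channel = ch,
                   sample_id = sample_id)
  }))
}

#' All-wild genotype for a panel
#'
#' @param panel a [melt_panel].
#' @param sample_id optional sample id column value.
#' @return Tibble with columns `locus_id`, `genotype` (plus `sample_id`
#'   when given).
#' @export
all_wild_genotype <- function(panel, sample_id = NULL) {
  gt <- tibble(
    locus_id = panel$loci$locus_id,
    genotype = ifelse(panel$loci$ploidy == "diploid", "WW",
                      "wild_homoplasmic"))
  if (!is.null(sample_id)) gt <- tibble(sample_id = sample_id, gt)
  gt
}

#' The 116-sample study fixture cohort
#'
#' Replays the published genotype composition of the 116-patient cohort:
#' 34 GJB2-positive samples (10 c.235delC homozygotes, 1 c.176-191del16
#' homozygote, 2 c.299_300delAT homozygotes, 6 + 3 + 1 compound
#' heterozygotes, 8 + 3 single-site heterozygotes), 15 SLC26A4-positive
#' samples (3 c.919-2A>G homozygotes, 4 c.919-2A>G/c.2168A>G compound
#' heterozygotes, 7 + 1 single-site heterozygotes) and 2 homoplasmic
#' m.1555A>G carriers, one of whom is also one of the
#' c.919-2A>G/c.2168A>G compound heterozygotes, so 50 distinct samples
#' carry at least one mutant allele and 66 are fully wild-type.
#'
#' @param panel a [melt_panel]; defaults to the bundled panel.
#' @return Long tibble with columns `sample_id`, `locus_id`, `genotype`
#'   (116 x 9 rows), with attribute `provenance = "fixture"`.
#' @examples
#' coh <- fixture_cohort()
#' length(unique(coh$sample_id))
#' @export
fixture_cohort <- function(panel = load_panel(melt2d_panel_file())) {
  n <- 116L
  ids <- sprintf("S%03d", seq_len(n))
  base <- bind_rows(lapply(ids, function(id) {
    all_wild_genotype(panel, sample_id = id)
  }))
  set_gt <- function(df, sample_idx, locus, gt) {
    sel <- df$sample_id %in% ids[sample_idx] & df$locus_id == locus
    df$genotype[sel] <- gt
    df
  }
  g <- base
  # GJB2 (34 positive): homozygotes
  g <- set_gt(g, 1:10, "c.235delC", "MM")
  g <- set_gt(g, 11, "c.176-191del16", "MM")
  g <- set_gt(g, 12:13, "c.299_300delAT", "MM")
  # GJB2 compound heterozygotes
  g <- set_gt(g, 14:19, "c.235delC", "WM")
  g <- set_gt(g, 14:19, "c.299_300delAT", "WM")
  g <- set_gt(g, 20:22, "c.235delC", "WM")
  g <- set_gt(g, 20:22, "c.176-191del16", "WM")
  g <- set_gt(g, 23, "c.176-191del16", "WM")
  g <- set_gt(g, 23, "c.299_300delAT", "WM")
  # GJB2 single-site heterozygotes
  g <- set_gt(g, 24:31, "c.235delC", "WM")
  g <- set_gt(g, 32:34, "c.299_300delAT", "WM")
  # SLC26A4 (15 positive)
  g <- set_gt(g, 35:37, "c.919-2A>G", "MM")
  g <- set_gt(g, 38:41, "c.919-2A>G", "WM")
  g <- set_gt(g, 38:41, "c.2168A>G", "WM")
  g <- set_gt(g, 42:48, "c.919-2A>G", "WM")
  g <- set_gt(g, 49, "c.2168A>G", "WM")
  # MT-RNR1: two homoplasmic m.1555A>G carriers, one overlapping the
  # SLC26A4 compound-heterozygote group (triple-mutation sample)
  g <- set_gt(g, c(38, 50), "m.1555A>G", "mutant_homoplasmic")
  attr(g, "provenance") <- "fixture"
  g
}

#' Sample a random cohort under Hardy-Weinberg equilibrium
#'
#' Diploid loci are drawn as two independent allele draws at the given
#' mutant-allele frequency; mitochondrial loci as a single Bernoulli draw
#' between the two homoplasmic states (heteroplasmy is representable by
#' the decoder but not sampled here).  Loci are independent.
#'
#' @param panel a [melt_panel].
#' @param n number of samples.
#' @param allele_frequencies named numeric vector, mutant-allele
#'   frequency per locus_id; loci not named get frequency 0.
#' @param seed optional integer seed.
#' @return Long tibble `sample_id`, `locus_id`, `genotype` with attribute
#'   `provenance = "sampled"`.
#' @export
sample_cohort <- function(panel, n, allele_frequencies = numeric(0),
                          seed = NULL) {
  stopifnot(inherits(panel, "melt_panel"), n >= 1)
  if (length(allele_frequencies) > 0L) {
    bad <- setdiff(names(allele_frequencies), panel$loci$locus_id)
    if (length(bad) > 0L) {
      stop(sprintf("frequency for unknown locus: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (any(allele_frequencies < 0 | allele_frequencies > 1)) {
      stop("allele frequencies must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n))
  out <- lapply(seq_len(nrow(panel$loci)), function(i) {
    loc <- panel$loci$locus_id[i]
    f <- if (loc %in% names(allele_frequencies)) {
      allele_frequencies[[loc]]
    } else 0
    if (panel$loci$ploidy[i] == "diploid") {
      k <- rbinom(n, 2L, f)
      gt <- c("WW", "WM", "MM")[k + 1L]
    } else {
      k <- rbinom(n, 1L, f)
      gt <- c("wild_homoplasmic", "mutant_homoplasmic")[k + 1L]
    }
    tibble(sample_id = ids, locus_id = loc, genotype = gt)
  })
  g <- arrange(bind_rows(out), sample_id)
  attr(g, "provenance") <- "sampled"
  g
}

#' Simulate melting traces for a whole cohort
#'
#' @param panel a [melt_panel].
#' @param cohort long genotype tibble (`sample_id`, `locus_id`,
#'   `genotype`) as produced by [fixture_cohort()] or [sample_cohort()].
#' @inheritParams simulate_sample
#' @return Long tibble of melting traces for every sample and channel.
#' @export
simulate_cohort <- function(panel, cohort, grid = melt_grid(),
                            noise_sd = 0.005, baseline_slope = -0.002,
                            width = 0.5,
                            channel_scale = c(FAM = 1, HEX = 1,
                                              Alexa568 = 1),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(cohort$sample_id)
  bind_rows(lapply(ids, function(id) {
    gt <- cohort[cohort$sample_id == id, c("locus_id", "genotype")]
    simulate_sample(panel, gt, sample_id = id, grid = grid,
                    noise_sd = noise_sd, baseline_slope = baseline_slope,
                    width = width, channel_scale = channel_scale,
                    seed = NULL)
  }))
}
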