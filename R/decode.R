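#' Match peak calls to panel allele coordinates
#'
#' Each peak is matched to the allele coordinate in the same channel
#' whose calibrated Tm lies within the panel tolerance; matching is
#' channel-local, so coordinates at the same temperature in different
#' channels (e.g. a wild FAM allele and a mutant HEX allele both at
#' 59.6 degrees C) never collide.  When two peaks compete for one
#' coordinate the closer peak wins and the loser is returned unassigned
#' with a QC flag.
#'
#' @param panel a [melt_panel].
#' @param peaks peak-call tibble for one sample (`channel`, `tm`,
#'   `height`, ...).
#' @return List with `evidence` (tibble `locus_id`, `allele`, `channel`,
#'   `peak_tm`, `height`, `delta_tm`), `unassigned` (peak rows that
#'   matched nothing or lost a competition) and `qc_flags` (character).
#' @examples
#' panel <- load_panel(melt2d_panel_file())
#' pk <- tibble::tibble(channel = "FAM", tm = 64.5, height = 1)
#' assign_peaks(panel, pk)$evidence
#' @export
assign_peaks <- function(panel, peaks) {
  stopifnot(inherits(panel, "melt_panel"))
  peaks <- as.data.frame(peaks)
  tol <- panel$tolerance_c
  co <- panel$coordinates
  flags <- character(0)

  if (nrow(peaks) == 0L) {
    return(list(evidence = tibble(locus_id = character(0),
                                  allele = character(0),
                                  channel = character(0),
                                  peak_tm = numeric(0),
                                  height = numeric(0),
                                  delta_tm = numeric(0)),
                unassigned = as_tibble(peaks), qc_flags = flags))
  }

  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    cand <- co[co$channel == peaks$channel[i], ]
    if (nrow(cand) == 0L) return(NULL)
    delta <- abs(cand$tm_c - peaks$tm[i])
    j <- which(delta <= tol)
    if (length(j) == 0L) return(NULL)
    # a validated panel spaces coordinates > 2*tol apart, so at most one
    # candidate can be in range; break pathological ties by delta
    j <- j[which.min(delta[j])]
    tibble(peak_row = i, locus_id = cand$locus_id[j],
           allele = cand$allele[j], channel = peaks$channel[i],
           peak_tm = peaks$tm[i],
           height = if ("height" %in% names(peaks)) peaks$height[i] else NA_real_,
           delta_tm = delta[j])
  })
  ev <- bind_rows(rows)

  unassigned_idx <- setdiff(seq_len(nrow(peaks)),
                            if (nrow(ev) > 0L) ev$peak_row else integer(0))
  if (nrow(ev) > 0L) {
    key <- paste(ev$locus_id, ev$allele)
    losers <- integer(0)
    for (k in unique(key[duplicated(key)])) {
      grp <- which(key == k)
      keep <- grp[which.min(ev$delta_tm[grp])]
      losers <- c(losers, setdiff(grp, keep))
      flags <- c(flags, sprintf("competing_peaks:%s", k))
    }
    if (length(losers) > 0L) {
      unassigned_idx <- sort(c(unassigned_idx, ev$peak_row[losers]))
      ev <- ev[-losers, ]
    }
  }
  if (length(unassigned_idx) > 0L) {
    flags <- c(flags, sprintf("unassigned_peak:%s@%.1f",
                              peaks$channel[unassigned_idx],
                              peaks$tm[unassigned_idx]))
  }
  list(evidence = ev[, setdiff(names(ev), "peak_row")],
       unassigned = as_tibble(peaks[unassigned_idx, , drop = FALSE]),
       qc_flags = flags)
}

#' Call per-locus genotypes from allele evidence
#'
#' Diploid loci: wild evidence only is `WW`, both alleles `WM`, mutant
#' only `MM`, neither `no_call`.  Mitochondrial loci: wild only is
#' `wild_homoplasmic`, mutant only `mutant_homoplasmic`, both
#' `heteroplasmic` (QC-flagged, since the assay validation cohorts showed
#' only homoplasmic states), neither `no_call`.  A `no_call` is itself a
#' QC failure: in a working multiplex every locus emits at least one
#' allele peak.
#'
#' @param panel a [melt_panel].
#' @param evidence the `evidence` tibble from [assign_peaks()].
#' @return List with `calls` (tibble `locus_id`, `genotype`) and
#'   `qc_flags` (character).
#' @export
call_genotypes <- function(panel, evidence) {
  stopifnot(inherits(panel, "melt_panel"))
  flags <- character(0)
  calls <- lapply(seq_len(nrow(panel$loci)), function(i) {
    loc <- panel$loci$locus_id[i]
    has_w <- any(evidence$locus_id == loc & evidence$allele == "wild")
    has_m <- any(evidence$locus_id == loc & evidence$allele == "mutant")
    diploid <- panel$loci$ploidy[i] == "diploid"
    gt <- if (has_w && has_m) {
      if (diploid) "WM" else "heteroplasmic"
    } else if (has_w) {
      if (diploid) "WW" else "wild_homoplasmic"
    } else if (has_m) {
      if (diploid) "MM" else "mutant_homoplasmic"
    } else {
      "no_call"
    }
    tibble(locus_id = loc, genotype = gt)
  })
  calls <- bind_rows(calls)
  for (loc in calls$locus_id[calls$genotype == "heteroplasmic"]) {
    flags <- c(flags, sprintf("heteroplasmy:%s", loc))
  }
  for (loc in calls$locus_id[calls$genotype == "no_call"]) {
    flags <- c(flags, sprintf("no_call:%s", loc))
  }
  list(calls = calls, qc_flags = flags)
}

#' QC check of the 48-degree HEX wild/mutant split
#'
#' In the bundled design every HEX peak below 48 degrees C belongs to a
#' wild allele (the mitochondrial wild coordinates) and every HEX peak
#' above it to a mutant allele.  A violation is only possible with a
#' mis-specified panel, so the check guards the panel/decoder contract.
#'
#' @param evidence the `evidence` tibble from [assign_peaks()].
#' @param hex_split_c split temperature (default 48).
#' @return List with `consistent` (logical) and `violations` (tibble of
#'   offending evidence rows).
#' @export
hex_threshold_check <- function(evidence, hex_split_c = 48) {
  hex <- evidence[evidence$channel == "HEX", , drop = FALSE]
  bad <- (hex$allele == "wild" & hex$peak_tm >= hex_split_c) |
    (hex$allele == "mutant" & hex$peak_tm <= hex_split_c)
  list(consistent = !any(bad), violations = as_tibble(hex[bad, , drop = FALSE]))
}

#' Enumerate the per-locus genotype class inventory of a panel
#'
#' Each diploid locus has classes `WW`/`WM`/`MM` and each mitochondrial
#' locus `wild_homoplasmic`/`mutant_homoplasmic`/`heteroplasmic`; the
#' bundled nine-locus panel therefore distinguishes 27 classes.
#'
#' @param panel a [melt_panel].
#' @return Tibble with columns `locus_id`, `genotype`.
#' @export
enumerate_genotype_classes <- function(panel) {
  stopifnot(inherits(panel, "melt_panel"))
  bind_rows(lapply(seq_len(nrow(panel$loci)), function(i) {
    cls <- if (panel$loci$ploidy[i] == "diploid") DIPLOID_CLASSES else MITO_CLASSES
    tibble(locus_id = panel$loci$locus_id[i], genotype = cls)
  }))
}

#' Decode one sample's peak calls into genotypes
#'
#' Runs [assign_peaks()], [call_genotypes()] and [hex_threshold_check()]
#' for a single sample.
#'
#' @param panel a [melt_panel].
#' @param peaks peak-call tibble for one sample.
#' @param sample_id sample identifier for the output.
#' @return List of class `sample_call` with `sample_id`, `calls`,
#'   `evidence`, `unassigned`, `qc_flags`, `hex_consistent`.
#' @export
decode_sample <- function(panel, peaks, sample_id = NA_character_) {
  asg <- assign_peaks(panel, peaks)
  gt <- call_genotypes(panel, asg$evidence)
  hex <- hex_threshold_check(asg$evidence)
  flags <- c(asg$qc_flags, gt$qc_flags)
  if (!hex$consistent) flags <- c(flags, "hex_split_violation")
  structure(list(sample_id = sample_id, calls = gt$calls,
                 evidence = asg$evidence, unassigned = asg$unassigned,
                 qc_flags = flags, hex_consistent = hex$consistent),
            class = "sample_call")
}

#' Full pipeline: melting traces to per-sample genotype calls
#'
#' Smooths and differentiates every (sample, channel) trace, detects
#' peaks, and decodes them against the panel.
#'
#' @param panel a [melt_panel].
#' @param traces long trace tibble (`sample_id`, `channel`,
#'   `temperature`, `fluorescence`).
#' @inheritParams call_peaks
#' @return Long tibble with columns `sample_id`, `locus_id`, `genotype`,
#'   `qc` (semicolon-joined flags, empty when clean).
#' @examples
#' panel <- load_panel(melt2d_panel_file())
#' tr <- simulate_sample(panel, all_wild_genotype(panel),
#'                       sample_id = "s1", noise_sd = 0, seed = 1)
#' call_cohort(panel, tr)
#' @export
call_cohort <- function(panel, traces, smooth_window = 0.5,
                        min_height_frac = 0.25, min_separation = 1.5,
                        floor_mult = 5, min_height_abs = NULL) {
  traces <- as.data.frame(traces)
  if (nrow(traces) == 0L) stop("no traces found", call. = FALSE)
  ids <- unique(traces$sample_id)
  bind_rows(lapply(ids, function(id) {
    pk <- call_peaks(traces[traces$sample_id == id, ],
                     smooth_window = smooth_window,
                     min_height_frac = min_height_frac,
                     min_separation = min_separation,
                     floor_mult = floor_mult,
                     min_height_abs = min_height_abs)
    sc <- decode_sample(panel, pk, sample_id = id)
    tibble(sample_id = id, sc$calls,
           qc = paste(sc$qc_flags, collapse = ";"))
  }))
}
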