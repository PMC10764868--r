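#' Construct a 2D-PCR panel object
#'
#' A panel places every allele of every locus at a unique point in
#' (channel, Tm) space and carries the oligo set that realises those
#' coordinates: one base-quenching probe per fluorescence channel, and per
#' allele a tagged forward primer (lowercase 5' tag homologous to the
#' channel probe, uppercase allele-specific 3' region) plus a shared
#' reverse primer.
#'
#' Structural invariants (unique `(locus, allele)` coordinates, Tm inside
#' the 30--70 degree acquisition window, valid DNA alphabet, one probe per
#' channel) are enforced here; assay-design rules that a miswired panel
#' could break (channel/allele polarity, the 48 degree HEX split,
#' within-channel Tm spacing) are checked separately by
#' [validate_channel_rules()] so that deliberately broken panels can be
#' constructed for testing.
#'
#' @param loci data frame with columns `gene`, `locus_id`,
#'   `ploidy` (`"diploid"` or `"mitochondrial"`).
#' @param probes data frame with columns `channel`, `label`, `sequence`.
#' @param coordinates data frame with columns `locus_id`, `allele`
#'   (`"wild"`/`"mutant"`), `channel`, `tm_c`.
#' @param oligos optional data frame with columns `locus_id`, `allele`,
#'   `channel`, `tag`, `specific_primer`, `artificial_mismatch_pos`,
#'   `reverse_primer`.
#' @param tolerance_c half-width (degrees C) of the Tm window used when
#'   matching an observed peak to a calibrated coordinate.
#' @param name panel name.
#' @return An object of class `melt_panel`.
#' @seealso [load_panel()], [validate_channel_rules()]
#' @export
melt_panel <- function(loci, probes, coordinates, oligos = NULL,
                       tolerance_c = 1.0, name = "panel") {
  loci <- as_tibble(loci)
  probes <- as_tibble(probes)
  coordinates <- as_tibble(coordinates)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0L) {
      stop(sprintf("panel %s missing field(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(loci, c("gene", "locus_id", "ploidy"), "loci")
  need(probes, c("channel", "label", "sequence"), "probes")
  need(coordinates, c("locus_id", "allele", "channel", "tm_c"), "coordinates")

  if (anyDuplicated(loci$locus_id)) {
    stop("duplicate locus_id in loci", call. = FALSE)
  }
  bad <- setdiff(loci$ploidy, c("diploid", "mitochondrial"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid ploidy value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  bad <- setdiff(probes$channel, MELT_CHANNELS)
  if (length(bad) > 0L) {
    stop(sprintf("invalid probe channel(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(probes$channel)) {
    stop("more than one probe assigned to a channel", call. = FALSE)
  }
  for (s in probes$sequence) assert_dna(s, "probe sequence")

  bad <- setdiff(coordinates$allele, c("wild", "mutant"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid allele value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  bad <- setdiff(coordinates$channel, probes$channel)
  if (length(bad) > 0L) {
    stop(sprintf("coordinate channel(s) without a probe: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  key <- paste(coordinates$locus_id, coordinates$allele)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (locus, allele) coordinate: %s",
                 paste(unique(key[duplicated(key)]), collapse = ", ")),
         call. = FALSE)
  }
  bad <- setdiff(coordinates$locus_id, loci$locus_id)
  if (length(bad) > 0L) {
    stop(sprintf("coordinate for unknown locus: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(coordinates$tm_c < 30 | coordinates$tm_c > 70)) {
    stop("coordinate tm_c outside the 30-70 degree acquisition window",
         call. = FALSE)
  }
  # every locus must expose both alleles
  for (loc in loci$locus_id) {
    have <- sort(coordinates$allele[coordinates$locus_id == loc])
    if (!identical(have, c("mutant", "wild"))) {
      stop(sprintf("locus %s must have exactly one wild and one mutant coordinate",
                   loc), call. = FALSE)
    }
  }

  if (!is.null(oligos)) {
    oligos <- as_tibble(oligos)
    need(oligos, c("locus_id", "allele", "channel", "tag",
                   "specific_primer", "reverse_primer"), "oligos")
    for (s in c(oligos$tag, oligos$specific_primer, oligos$reverse_primer)) {
      assert_dna(s, "oligo sequence")
    }
    probe_len <- nchar(probes$sequence)
    names(probe_len) <- probes$channel
    bad <- nchar(oligos$tag) != probe_len[oligos$channel]
    if (any(bad)) {
      stop(sprintf("tag length differs from channel probe length for: %s",
                   paste(oligos$locus_id[bad], collapse = ", ")),
           call. = FALSE)
    }
  }

  structure(
    list(name = name, tolerance_c = tolerance_c, loci = loci,
         probes = probes, coordinates = coordinates, oligos = oligos),
    class = "melt_panel"
  )
}

assert_dna <- function(s, what) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L ||
      grepl("[^ACGTacgt]", s)) {
    stop(sprintf("%s is not a non-empty A/C/G/T string: %s", what,
                 deparse(substitute(s))), call. = FALSE)
  }
  invisible(s)
}

#' Load a panel definition from a YAML/JSON config file
#'
#' The schema is a single document with keys `name`, `tolerance_c`,
#' `loci[]`, `probes[]`, `coordinates[]`, `oligos[]`.  The bundled
#' nine-locus hearing-loss panel ships as
#' `system.file("extdata", "panels", "deafness9.yaml", package = "melt2d")`.
#'
#' @param path path to the panel config file.
#' @return A validated [melt_panel] object.
#' @examples
#' panel <- load_panel(melt2d_panel_file())
#' panel
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("panel config not found: %s", path), call. = FALSE)
  }
  doc <- yaml::read_yaml(path)
  for (k in c("loci", "probes", "coordinates")) {
    if (is.null(doc[[k]])) {
      stop(sprintf("panel config missing key '%s'", k), call. = FALSE)
    }
  }
  as_df <- function(x) bind_rows(lapply(x, function(row) {
    as_tibble(lapply(row, function(v) if (is.null(v)) NA else v))
  }))
  oligos <- if (!is.null(doc$oligos)) as_df(doc$oligos) else NULL
  melt_panel(
    loci = as_df(doc$loci),
    probes = as_df(doc$probes),
    coordinates = as_df(doc$coordinates),
    oligos = oligos,
    tolerance_c = doc$tolerance_c %||% 1.0,
    name = doc$name %||% basename(path)
  )
}

#' Path to the bundled nine-locus hearing-loss panel config
#' @return File path of `deafness9.yaml`.
#' @export
melt2d_panel_file <- function() {
  system.file("extdata", "panels", "deafness9.yaml", package = "melt2d",
              mustWork = TRUE)
}

#' @export
print.melt_panel <- function(x, ...) {
  cat(sprintf("<melt_panel '%s'>  %d loci, %d coordinates, %d probes, tolerance +/- %.1f C\n",
              x$name, nrow(x$loci), nrow(x$coordinates), nrow(x$probes),
              x$tolerance_c))
  print(x$coordinates, n = nrow(x$coordinates))
  invisible(x)
}

panel_coordinate <- function(panel, locus_id, allele) {
  co <- panel$coordinates
  co[co$locus_id == locus_id & co$allele == allele, ]
}

panel_ploidy <- function(panel, locus_id) {
  panel$loci$ploidy[match(locus_id, panel$loci$locus_id)]
}

#' Check the assay-design rules of a panel
#'
#' Verifies the decoding conventions of the three-channel readout:
#' every FAM coordinate is a wild allele; every Alexa568 coordinate is a
#' mutant allele; HEX wild coordinates melt below 48 degrees C and HEX
#' mutant coordinates above it; and within each channel any two
#' coordinates are separated by more than twice the matching tolerance,
#' so Tm windows cannot overlap.
#'
#' @param panel a [melt_panel].
#' @param hex_split_c temperature splitting HEX wild from mutant
#'   coordinates (default 48).
#' @return A list of class `panel_validation` with elements `pass`
#'   (logical), `violations` (character), and `channel_gaps` (tibble of
#'   per-channel minimum Tm gaps).
#' @examples
#' rep <- validate_channel_rules(load_panel(melt2d_panel_file()))
#' rep$pass
#' @export
validate_channel_rules <- function(panel, hex_split_c = 48) {
  stopifnot(inherits(panel, "melt_panel"))
  co <- panel$coordinates
  v <- character(0)

  bad <- co$locus_id[co$channel == "FAM" & co$allele != "wild"]
  if (length(bad) > 0L) {
    v <- c(v, sprintf("FAM coordinate is not a wild allele: %s",
                      paste(bad, collapse = ", ")))
  }
  bad <- co$locus_id[co$channel == "Alexa568" & co$allele != "mutant"]
  if (length(bad) > 0L) {
    v <- c(v, sprintf("Alexa568 coordinate is not a mutant allele: %s",
                      paste(bad, collapse = ", ")))
  }
  bad <- co$locus_id[co$channel == "HEX" & co$allele == "wild" &
                       co$tm_c >= hex_split_c]
  if (length(bad) > 0L) {
    v <- c(v, sprintf("HEX wild coordinate at or above %.0f C: %s",
                      hex_split_c, paste(bad, collapse = ", ")))
  }
  bad <- co$locus_id[co$channel == "HEX" & co$allele == "mutant" &
                       co$tm_c <= hex_split_c]
  if (length(bad) > 0L) {
    v <- c(v, sprintf("HEX mutant coordinate at or below %.0f C: %s",
                      hex_split_c, paste(bad, collapse = ", ")))
  }

  gaps <- lapply(unique(co$channel), function(ch) {
    tms <- sort(co$tm_c[co$channel == ch])
    tibble(channel = ch,
           min_gap_c = if (length(tms) > 1L) min(diff(tms)) else Inf)
  })
  gaps <- bind_rows(gaps)
  tight <- gaps$channel[gaps$min_gap_c <= 2 * panel$tolerance_c]
  if (length(tight) > 0L) {
    v <- c(v, sprintf(
      "within-channel Tm gap not greater than 2 x tolerance (%.1f C) in: %s",
      2 * panel$tolerance_c, paste(tight, collapse = ", ")))
  }

  structure(list(pass = length(v) == 0L, violations = v,
                 channel_gaps = gaps, hex_split_c = hex_split_c),
            class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  cat(sprintf("<panel_validation>  %s\n", if (x$pass) "PASS" else "FAIL"))
  print(x$channel_gaps)
  if (!x$pass) cat(paste0("  - ", x$violations, collapse = "\n"), "\n")
  invisible(x)
}

#' Compare a primer tag with its channel probe
#'
#' Tags are homologous to the channel probe up to a small number of
#' deliberate mismatches; fewer mismatches give a more stable tag--probe
#' duplex and hence a higher melting temperature.  Comparison is
#' case-insensitive and position indices are 1-based from the 5' end.
#'
#' @param tag,probe equal-length DNA strings.
#' @return A list with `n_mismatch` and integer `positions`.
#' @examples
#' tag_probe_mismatches("acgt", "acct")
#' @export
tag_probe_mismatches <- function(tag, probe) {
  assert_dna(tag, "tag")
  assert_dna(probe, "probe")
  if (nchar(tag) != nchar(probe)) {
    stop(sprintf("tag (%d nt) and probe (%d nt) differ in length",
                 nchar(tag), nchar(probe)), call. = FALSE)
  }
  a <- strsplit(tolower(tag), "")[[1]]
  b <- strsplit(tolower(probe), "")[[1]]
  pos <- which(a != b)
  list(n_mismatch = length(pos), positions = pos)
}

#' Check the ARMS design of an allele-specific primer
#'
#' In ARMS (amplification refractory mutation system) priming the
#' 3'-terminal base of the allele-specific primer pairs only with its
#' target allele; specificity is commonly reinforced by an artificial
#' mismatch engineered a few bases in from the 3' end.  This check
#' verifies (a) that the primer's 3'-terminal base is the expected
#' discriminating base and (b), when a template context is supplied, that
#' every primer/template mismatch other than the terminal base falls
#' within the allowed position window (counted from the 3' end, terminal
#' base = position 1).
#'
#' @param oligo an oligo record (row of `panel$oligos`) or a DNA string
#'   giving the allele-specific primer 3' region.
#' @param expected_3prime_base single nucleotide the primer must end in.
#' @param template optional DNA string; its 3'-terminal region is aligned
#'   to the primer end-to-end.
#' @param mismatch_positions_allowed integer positions (from the 3' end)
#'   where artificial mismatches are permitted; default 3:6.
#' @return A list with `three_prime_ok`, `mismatch_positions` (from the
#'   3' end, excluding position 1; `NULL` without a template),
#'   `mismatch_ok` (`NA` without a template) and `pass`.
#' @examples
#' check_arms_design("ACGTACCG", "G")
#' @export
check_arms_design <- function(oligo, expected_3prime_base,
                              template = NULL,
                              mismatch_positions_allowed = 3:6) {
  primer <- if (is.character(oligo)) oligo else oligo$specific_primer
  if (is.null(primer) || length(primer) != 1L || is.na(primer) ||
      nchar(primer) == 0L) {
    stop("empty allele-specific primer", call. = FALSE)
  }
  assert_dna(primer, "primer")
  expected_3prime_base <- toupper(expected_3prime_base)
  stopifnot(expected_3prime_base %in% c("A", "C", "G", "T"))
  last <- toupper(substr(primer, nchar(primer), nchar(primer)))
  three_prime_ok <- identical(last, expected_3prime_base)

  mismatch_positions <- NULL
  mismatch_ok <- NA
  if (!is.null(template)) {
    assert_dna(template, "template")
    np <- nchar(primer)
    if (nchar(template) < np) {
      stop("template shorter than primer", call. = FALSE)
    }
    tmpl3 <- substr(template, nchar(template) - np + 1L, nchar(template))
    p <- strsplit(tolower(primer), "")[[1]]
    t3 <- strsplit(tolower(tmpl3), "")[[1]]
    # positions counted from the 3' end; drop the discriminating base itself
    from3 <- np - which(p != t3) + 1L
    mismatch_positions <- sort(setdiff(from3, 1L))
    mismatch_ok <- all(mismatch_positions %in% mismatch_positions_allowed)
  }

  list(three_prime_ok = three_prime_ok,
       mismatch_positions = mismatch_positions,
       mismatch_ok = mismatch_ok,
       pass = three_prime_ok && !isFALSE(mismatch_ok))
}
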