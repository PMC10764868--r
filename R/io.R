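#' Read melting traces from a long-format CSV file
#'
#' The native dialect is long format with one row per acquisition point:
#' `sample_id`, `channel`, `temperature`, `fluorescence`.  Instrument
#' exports using other column names can be mapped with `column_map`.
#' Rows may appear in any order; traces are grouped by (sample, channel)
#' and sorted by temperature.
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping the required names
#'   to the file's column names, e.g.
#'   `c(temperature = "Temp", fluorescence = "F1")`.
#' @return Long trace tibble with the standard column names.
#' @export
read_melt_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  req <- c("sample_id", "channel", "temperature", "fluorescence")
  map <- stats::setNames(req, req)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  miss <- map[!map %in% names(df)]
  if (length(miss) > 0L) {
    stop(sprintf("missing column(s): %s",
                 paste(sprintf("%s (mapped to '%s')", miss, names(miss)),
                       collapse = ", ")), call. = FALSE)
  }
  out <- tibble(sample_id = df[[map["sample_id"]]],
                channel = df[[map["channel"]]],
                temperature = suppressWarnings(as.numeric(df[[map["temperature"]]])),
                fluorescence = suppressWarnings(as.numeric(df[[map["fluorescence"]]])))
  for (col in c("temperature", "fluorescence")) {
    bad <- which(is.na(out[[col]]) & !is.na(df[[map[col]]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric %s value at data row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  if (nrow(out) == 0L) stop("no traces found", call. = FALSE)
  out <- arrange(out, .data$sample_id, .data$channel, .data$temperature)
  key <- paste(out$sample_id, out$channel)
  for (k in unique(key)) {
    tt <- out$temperature[key == k]
    if (any(diff(tt) <= 0)) {
      stop(sprintf("non-increasing temperature grid in trace %s", k),
           call. = FALSE)
    }
  }
  out
}

#' Write melting traces to long-format CSV
#' @param traces long trace tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_melt_csv <- function(traces, path) {
  readr::write_csv(traces[, c("sample_id", "channel", "temperature",
                              "fluorescence")], path)
  invisible(path)
}

#' Format a genotype class in slash notation
#'
#' Diploid: `wt/wt`, `<locus>/wt`, `<locus>/<locus>`.  Mitochondrial:
#' `wt`, `<locus>` (homoplasmic), `<locus>/wt` (heteroplasmic).
#' `no_call` and `conflict` pass through unchanged.
#'
#' @param locus_id locus identifier.
#' @param genotype genotype class string.
#' @param ploidy `"diploid"` or `"mitochondrial"`.
#' @return Character notation.
#' @export
format_genotype <- function(locus_id, genotype, ploidy) {
  mapply(function(loc, gt, pl) {
    if (gt %in% NOCALL_CLASSES) return(gt)
    if (pl == "diploid") {
      switch(gt,
             WW = "wt/wt",
             WM = paste0(loc, "/wt"),
             MM = paste0(loc, "/", loc),
             stop(sprintf("invalid diploid class '%s'", gt), call. = FALSE))
    } else {
      switch(gt,
             wild_homoplasmic = "wt",
             mutant_homoplasmic = loc,
             heteroplasmic = paste0(loc, "/wt"),
             stop(sprintf("invalid mitochondrial class '%s'", gt),
                  call. = FALSE))
    }
  }, locus_id, genotype, ploidy, USE.NAMES = FALSE)
}

#' Parse slash-notation genotypes back to class codes
#' @param text notation string(s) as written by [format_genotype()].
#' @param locus_id locus identifier(s).
#' @param ploidy ploidy value(s).
#' @return Genotype class string(s).
#' @export
parse_genotype <- function(text, locus_id, ploidy) {
  mapply(function(tx, loc, pl) {
    if (tx %in% NOCALL_CLASSES) return(tx)
    if (pl == "diploid") {
      if (tx == "wt/wt") return("WW")
      if (tx == paste0(loc, "/wt")) return("WM")
      if (tx == paste0(loc, "/", loc)) return("MM")
    } else {
      if (tx == "wt") return("wild_homoplasmic")
      if (tx == loc) return("mutant_homoplasmic")
      if (tx == paste0(loc, "/wt")) return("heteroplasmic")
    }
    stop(sprintf("cannot parse genotype '%s' at locus %s", tx, loc),
         call. = FALSE)
  }, text, locus_id, ploidy, USE.NAMES = FALSE)
}

#' Write genotype calls to a wide TSV
#'
#' One row per sample, one column per panel locus in slash notation,
#' plus a `qc` column when QC flags are present.
#'
#' @param calls long call tibble (`sample_id`, `locus_id`, `genotype`,
#'   optional `qc`).
#' @param path output path.
#' @param panel a [melt_panel].
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(calls, path,
                               panel = load_panel(melt2d_panel_file())) {
  calls <- as.data.frame(calls)
  ids <- unique(calls$sample_id)
  loci <- panel$loci$locus_id
  wide <- lapply(ids, function(id) {
    sub <- calls[calls$sample_id == id, ]
    row <- list(sample_id = id)
    for (loc in loci) {
      gt <- sub$genotype[sub$locus_id == loc]
      if (length(gt) != 1L) {
        stop(sprintf("sample %s has %d calls at locus %s", id,
                     length(gt), loc), call. = FALSE)
      }
      row[[loc]] <- format_genotype(loc, gt, panel_ploidy(panel, loc))
    }
    if ("qc" %in% names(sub)) row$qc <- sub$qc[1]
    as_tibble(row)
  })
  readr::write_tsv(bind_rows(wide), path)
  invisible(path)
}

#' Read genotype calls from a wide TSV
#' @param path TSV path as written by [write_genotype_tsv()].
#' @param panel a [melt_panel].
#' @return Long call tibble (`sample_id`, `locus_id`, `genotype`,
#'   optional `qc`).
#' @export
read_genotype_tsv <- function(path, panel = load_panel(melt2d_panel_file())) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!"sample_id" %in% names(df)) {
    stop("missing column: sample_id", call. = FALSE)
  }
  loci <- intersect(panel$loci$locus_id, names(df))
  miss <- setdiff(panel$loci$locus_id, loci)
  if (length(miss) > 0L) {
    stop(sprintf("missing locus column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- bind_rows(lapply(seq_len(nrow(df)), function(i) {
    g <- tibble(
      sample_id = df$sample_id[i], locus_id = loci,
      genotype = parse_genotype(unlist(df[i, loci]), loci,
                                panel_ploidy(panel, loci)))
    if ("qc" %in% names(df)) {
      g$qc <- if (is.na(df$qc[i])) "" else df$qc[i]
    }
    g
  }))
  out
}

#' Write a cohort summary as TSV tables and JSON
#'
#' Writes `<prefix>_genotypes.tsv` (per-gene genotype categories),
#' `<prefix>_frequencies.tsv` (per-site allele frequencies) and
#' `<prefix>_summary.json` (the full summary object).
#'
#' @param summary a `cohort_summary` from [summarize_cohort()].
#' @param prefix output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_summary <- function(summary, prefix) {
  stopifnot(inherits(summary, "cohort_summary"))
  f1 <- paste0(prefix, "_genotypes.tsv")
  f2 <- paste0(prefix, "_frequencies.tsv")
  f3 <- paste0(prefix, "_summary.json")
  readr::write_tsv(summary$gene_genotypes, f1)
  readr::write_tsv(summary$site_frequencies, f2)
  jsonlite::write_json(
    list(n_samples = summary$n_samples,
         overall = summary$overall,
         gene_positivity = summary$gene_positivity,
         gene_categories = summary$gene_categories,
         gene_genotypes = summary$gene_genotypes,
         site_frequencies = summary$site_frequencies),
    f3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f1, f2, f3))
}
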