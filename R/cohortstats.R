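#' Summarise a fully-genotyped cohort
#'
#' Aggregates per-sample, per-locus genotype calls into the study-style
#' epidemiological outputs: per-gene genotype categories (homozygous,
#' compound heterozygous, single-site heterozygous, homoplasmic),
#' per-gene positivity, per-site allele counts and frequencies, and the
#' overall carrier rate.  Counting rules: gene positivity counts samples
#' with at least one mutant allele in that gene; compound heterozygotes
#' carry two different heterozygous mutant sites within one gene; the
#' overall carrier count deduplicates samples positive in several genes;
#' mutant-allele counts are het + 2 x hom over a denominator of 2n for
#' diploid loci, and carrier counts over n for mitochondrial loci.
#' Heterozygotes for different genes are counted separately per site.
#'
#' @param calls long tibble (`sample_id`, `locus_id`, `genotype`); every
#'   sample must be fully called (`no_call`/`conflict` entries are an
#'   error).
#' @param panel a [melt_panel].
#' @return A list of class `cohort_summary`: `n_samples`,
#'   `gene_genotypes` (gene x category x genotype label counts),
#'   `gene_categories` (per-gene category subtotals with percent),
#'   `gene_positivity`, `site_frequencies`, `overall` (carrier count and
#'   percent).
#' @examples
#' summarize_cohort(fixture_cohort())
#' @export
summarize_cohort <- function(calls, panel = load_panel(melt2d_panel_file())) {
  stopifnot(inherits(panel, "melt_panel"))
  calls <- as.data.frame(calls)
  bad <- setdiff(calls$locus_id, panel$loci$locus_id)
  if (length(bad) > 0L) {
    stop(sprintf("unknown locus in input: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(calls$genotype %in% NOCALL_CLASSES)) {
    stop("cohort contains no_call/conflict genotypes; resolve QC first",
         call. = FALSE)
  }
  ids <- unique(calls$sample_id)
  n <- length(ids)
  pct <- function(k) if (n == 0L) NA_real_ else round(100 * k / n, 1)

  # ---- per-site allele counts (Table-5 style) ----
  site <- bind_rows(lapply(seq_len(nrow(panel$loci)), function(i) {
    loc <- panel$loci$locus_id[i]
    g <- calls$genotype[calls$locus_id == loc]
    diploid <- panel$loci$ploidy[i] == "diploid"
    het <- sum(g %in% c("WM", "heteroplasmic"))
    hom <- sum(g %in% c("MM", "mutant_homoplasmic"))
    if (diploid) {
      alleles <- het + 2L * hom
      denom <- 2L * n
    } else {
      alleles <- het + hom  # carrier count on the haploid denominator
      denom <- n
    }
    tibble(gene = panel$loci$gene[i], locus_id = loc,
           het = het, hom = hom, mutant_alleles = alleles,
           denominator = denom,
           freq_pct = if (denom == 0L) NA_real_ else
             round(100 * alleles / denom, 1))
  }))

  # ---- per-sample, per-gene category + genotype label ----
  classify <- function(sub) {
    # sub: calls of one sample restricted to one gene, in panel order
    mm <- sub$locus_id[sub$genotype == "MM"]
    wm <- sub$locus_id[sub$genotype == "WM"]
    hom_mt <- sub$locus_id[sub$genotype == "mutant_homoplasmic"]
    het_mt <- sub$locus_id[sub$genotype == "heteroplasmic"]
    if (length(hom_mt) > 0L) {
      return(c("homoplasmic", paste(hom_mt, collapse = "+")))
    }
    if (length(het_mt) > 0L) {
      return(c("heteroplasmic", paste(paste0(het_mt, "/wt"), collapse = "+")))
    }
    if (length(mm) > 0L) {
      lab <- c(paste0(mm, "/", mm), if (length(wm)) paste0(wm, "/wt"))
      return(c("homozygous", paste(lab, collapse = "+")))
    }
    if (length(wm) >= 2L) {
      return(c("compound heterozygous", paste(wm, collapse = "/")))
    }
    if (length(wm) == 1L) {
      return(c("heterozygous", paste0(wm, "/wt")))
    }
    c(NA_character_, NA_character_)
  }

  per_sample <- list()
  for (gene in unique(panel$loci$gene)) {
    gene_loci <- panel$loci$locus_id[panel$loci$gene == gene]
    for (id in ids) {
      sub <- calls[calls$sample_id == id & calls$locus_id %in% gene_loci, ]
      sub <- sub[match(gene_loci, sub$locus_id), ]
      cl <- classify(sub)
      if (!is.na(cl[1])) {
        per_sample[[length(per_sample) + 1L]] <-
          tibble(sample_id = id, gene = gene,
                 category = cl[1], label = cl[2])
      }
    }
  }
  per_sample <- if (length(per_sample)) bind_rows(per_sample) else
    tibble(sample_id = character(0), gene = character(0),
           category = character(0), label = character(0))

  gene_genotypes <- summarise(
    group_by(per_sample, .data$gene, .data$category, .data$label),
    n = dplyr::n(), .groups = "drop")
  gene_categories <- summarise(
    group_by(per_sample, .data$gene, .data$category),
    n = dplyr::n(), .groups = "drop")
  gene_categories$pct <- pct(gene_categories$n)
  gene_positivity <- summarise(
    group_by(per_sample, .data$gene),
    n_positive = length(unique(.data$sample_id)), .groups = "drop")
  gene_positivity$pct <- pct(gene_positivity$n_positive)

  carriers <- unique(per_sample$sample_id)
  overall <- list(n_carriers = length(carriers),
                  pct = pct(length(carriers)))

  structure(list(n_samples = n, gene_genotypes = gene_genotypes,
                 gene_categories = gene_categories,
                 gene_positivity = gene_positivity,
                 site_frequencies = site, overall = overall,
                 carrier_ids = carriers),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary>  %d samples, %d carriers (%.1f%%)\n",
              x$n_samples, x$overall$n_carriers, x$overall$pct))
  cat("-- genotype categories --\n")
  print(x$gene_genotypes, n = nrow(x$gene_genotypes))
  cat("-- allele frequencies --\n")
  print(x$site_frequencies, n = nrow(x$site_frequencies))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's statistic without continuity correction, df = 1, on the
#' table `rbind(c(a, b), c(c, d))`.
#'
#' @param a,b,c,d non-negative integer cell counts; all four margins
#'   must be positive.
#' @return List with `statistic`, `df` (always 1) and `p_value`.
#' @examples
#' chi_square_2x2(37, 195, 721, 5287)$statistic
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop("all margins of the 2x2 table must be positive", call. = FALSE)
  }
  # double arithmetic: (ad - bc)^2 overflows 32-bit integers easily
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Compare a local rate with a published external rate
#'
#' Reconstructs the external 2x2 cell counts from a published percentage
#' and cohort size, then applies the Pearson chi-square test.  For
#' allele-based comparisons at nuclear loci the external patient count is
#' doubled to an allele denominator; the external positive count is the
#' published rate times that denominator, rounded to the nearest
#' integer.  Because the external count is reconstructed from a rounded
#' percentage, statistics can differ from values computed on the
#' original (unpublished) counts by a few hundredths.
#'
#' @param local_k,local_n local positive count and denominator (alleles
#'   or carriers, per `basis`).
#' @param external_rate_percent published external rate in percent.
#' @param external_n external cohort size in patients.
#' @param basis `"allele"` (external denominator 2 x patients) or
#'   `"carrier"` (external denominator = patients).
#' @param site optional label carried into the output.
#' @return A one-row tibble of class `region_comparison` with the local
#'   and reconstructed external counts, `chi_square`, `df`, `p_value`.
#' @examples
#' compare_with_region(37, 232, 12.0, 3004, basis = "allele")
#' @export
compare_with_region <- function(local_k, local_n, external_rate_percent,
                                external_n, basis = c("allele", "carrier"),
                                site = NA_character_) {
  basis <- match.arg(basis)
  if (external_rate_percent < 0 || external_rate_percent > 100) {
    stop("external_rate_percent must lie in [0, 100]", call. = FALSE)
  }
  if (external_n <= 0) stop("external_n must be positive", call. = FALSE)
  ext_denom <- if (basis == "allele") 2L * external_n else external_n
  ext_k <- round(external_rate_percent * ext_denom / 100)
  cs <- chi_square_2x2(local_k, local_n - local_k, ext_k, ext_denom - ext_k)
  structure(
    tibble(site = site, basis = basis, local_k = local_k,
           local_n = local_n,
           local_rate_pct = round(100 * local_k / local_n, 1),
           external_rate_pct = external_rate_percent,
           external_k = ext_k, external_n = ext_denom,
           chi_square = cs$statistic, df = cs$df, p_value = cs$p_value),
    class = c("region_comparison", class(tibble())))
}

#' Cohen's kappa between two genotype call sets
#'
#' Pooled over all (sample, locus) labels.  Kappa is `(po - pe) /
#' (1 - pe)` with observed agreement `po` and chance agreement `pe`; it
#' is defined as 1 whenever observed agreement is total, including the
#' degenerate single-category case where `pe = 1`.  The p-value tests
#' kappa = 0 with the large-sample normal approximation.
#'
#' @param calls_a,calls_b long call tibbles (`sample_id`, `locus_id`,
#'   `genotype`) over identical (sample, locus) keys.
#' @return List of class `kappa_test` with `kappa`, `po`, `pe`, `n`,
#'   `z`, `p_value`.
#' @examples
#' coh <- fixture_cohort()
#' cohens_kappa(coh, coh)$kappa
#' @export
cohens_kappa <- function(calls_a, calls_b) {
  a <- as.data.frame(calls_a)
  b <- as.data.frame(calls_b)
  a <- a[order(a$sample_id, a$locus_id), ]
  b <- b[order(b$sample_id, b$locus_id), ]
  if (nrow(a) != nrow(b) ||
      !identical(paste(a$sample_id, a$locus_id),
                 paste(b$sample_id, b$locus_id))) {
    stop("call sets cover different (sample, locus) keys", call. = FALSE)
  }
  n <- nrow(a)
  if (n == 0L) stop("empty call sets", call. = FALSE)
  labs <- union(a$genotype, b$genotype)
  pa <- table(factor(a$genotype, levels = labs)) / n
  pb <- table(factor(b$genotype, levels = labs)) / n
  po <- mean(a$genotype == b$genotype)
  pe <- sum(pa * pb)
  kappa <- if (po == 1) 1 else (po - pe) / (1 - pe)
  # H0 variance of kappa (Fleiss); degenerate when pe = 1
  if (pe < 1) {
    se0 <- sqrt(pe + pe^2 - sum(pa * pb * (pa + pb))) / ((1 - pe) * sqrt(n))
    z <- kappa / se0
    p <- 2 * pnorm(-abs(z))
  } else {
    z <- NA_real_
    p <- NA_real_
  }
  structure(list(kappa = kappa, po = po, pe = pe, n = n, z = z,
                 p_value = p),
            class = "kappa_test")
}

#' @export
print.kappa_test <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f  (n = %d pairs, observed agreement %.3f, P %s)\n",
              x$kappa, x$n, x$po, format_p(x$p_value)))
  invisible(x)
}

# render small p-values the way reports print them
format_p <- function(p) {
  if (is.na(p)) return("= NA")
  if (p < 0.001) "< 0.001" else sprintf("= %.3f", p)
}
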