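#' Normalize metagenome gene-hit counts
#'
#' Hit counts from screening assembled contigs or unassembled reads against
#' representative clade sequences are made comparable across genes of
#' different lengths: `assembled` mode divides by gene length in kb
#' (hits/kb); `unassembled` mode additionally divides by the library size
#' in millions of reads (hits/kb/Mread, the RPKM-like convention).
#'
#' @param hits Data frame with columns `clade`, `length_bp`, `hit_count`
#'   (as from [simulate_gene_hits()] or [read_gene_hits()]).
#' @param mode `"assembled"` or `"unassembled"`.
#' @param total_reads Library read count; required for `"unassembled"`.
#' @return Data frame with columns `clade` and `abundance`, carrying a
#'   `mode` attribute.
#' @examples
#' h <- data.frame(clade = "xoxF5", length_bp = 1000, hit_count = 10)
#' normalize_gene_abundance(h, "assembled") # 10 hits/kb
#' @export
normalize_gene_abundance <- function(hits,
                                     mode = c("assembled", "unassembled"),
                                     total_reads = NULL) {
  mode <- match.arg(mode)
  if (any(hits$length_bp <= 0)) {
    stop("reference gene lengths must be positive", call. = FALSE)
  }
  if (any(hits$hit_count < 0)) {
    stop("hit counts must be non-negative", call. = FALSE)
  }
  abundance <- hits$hit_count / (hits$length_bp / 1000)
  if (mode == "unassembled") {
    if (is.null(total_reads)) {
      stop("total_reads is required to normalize unassembled-read hits",
           call. = FALSE)
    }
    abundance <- abundance / (total_reads / 1e6)
  }
  out <- data.frame(clade = hits$clade, abundance = abundance,
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

#' recA-relative percentage of bacteria carrying a methanol dehydrogenase
#'
#' Expresses the summed normalized abundance of methanol-dehydrogenase
#' clades as a percentage of the normalized abundance of the
#' near-universal single-copy housekeeping gene recA. Because several
#' genomes carry multiple MDH genes (notably multiple xoxF5 copies),
#' values above 100% are legitimate and flagged rather than rejected. All
#' abundances must come from the same normalization mode.
#'
#' @param mdh_abundances Data frame from [normalize_gene_abundance()]
#'   restricted to MDH clades.
#' @param recA_abundance Normalized recA abundance (scalar, or a one-row
#'   data frame with an `abundance` column).
#' @return List with `percentage` and logical `multi_copy` (TRUE above
#'   100%).
#' @export
mdh_bacterial_fraction <- function(mdh_abundances, recA_abundance) {
  if (is.data.frame(recA_abundance)) {
    recA_abundance <- recA_abundance$abundance
  }
  if (length(recA_abundance) != 1L || !is.finite(recA_abundance) ||
      recA_abundance <= 0) {
    stop("recA abundance must be a single positive value; the percentage is ",
         "undefined otherwise", call. = FALSE)
  }
  pct <- 100 * sum(mdh_abundances$abundance) / recA_abundance
  list(percentage = pct, multi_copy = pct > 100)
}

#' Calibrate a clade-specific BLAST e-value cutoff
#'
#' Chooses the stringency for a clade screen as the e-value of the
#' strongest hit to any *other* clade: hits with e-value strictly below
#' that threshold pass, so the passing set can never contain an
#' incorrect-clade sequence, and no looser threshold has that property.
#' With no incorrect-clade hits the threshold is `+Inf` (everything
#' passes). If the strongest hit overall is from the wrong clade the
#' returned threshold passes zero hits, with a warning.
#'
#' @param hits Data frame with columns `e_value` and `clade` (the true
#'   clade of each hit sequence).
#' @param query_clade Clade being screened for.
#' @return The e-value threshold (numeric scalar); hits pass iff
#'   `e_value < threshold`.
#' @examples
#' h <- data.frame(e_value = c(1e-50, 1e-10, 1e-8),
#'                 clade = c("xoxF5", "xoxF5", "xoxF3"))
#' calibrate_evalue_cutoff(h, "xoxF5") # 1e-8; two xoxF5 hits pass
#' @export
calibrate_evalue_cutoff <- function(hits, query_clade) {
  if (nrow(hits) == 0L) stop("empty hit list", call. = FALSE)
  wrong <- hits$e_value[hits$clade != query_clade]
  threshold <- if (length(wrong) == 0L) Inf else min(wrong)
  if (sum(hits$e_value < threshold & hits$clade == query_clade) == 0L) {
    warning("strongest hit is from the incorrect clade; calibrated threshold ",
            "passes zero hits", call. = FALSE)
  }
  threshold
}

#' Fit a qPCR standard curve
#'
#' Least-squares regression of quantification cycle (Cq) on log10 copy
#' number over a dilution series (the assay uses standards from 1e8 down
#' to 1e1 copies/ul). Amplification efficiency is derived from the slope
#' as `10^(-1/slope) - 1`; a perfect doubling per cycle gives slope
#' -3.3219 and efficiency 100%.
#'
#' @param dilution_series Data frame with columns `copies` (template
#'   copies, > 0) and `cq`; technical replicates may share a copy level.
#' @return Object of class `qpcr_curve`: `slope` (Cq per log10 copies),
#'   `intercept` (Cq at 1 copy), `efficiency` (fraction, e.g. 0.98),
#'   `efficiency_percent`, `r_squared`, `n_levels`.
#' @export
fit_standard_curve <- function(dilution_series) {
  if (!all(c("copies", "cq") %in% names(dilution_series))) {
    stop("dilution series needs 'copies' and 'cq' columns", call. = FALSE)
  }
  if (any(dilution_series$copies <= 0)) {
    stop("copy numbers must be positive", call. = FALSE)
  }
  if (length(unique(dilution_series$copies)) < 3L) {
    stop("at least 3 distinct copy-number levels are required",
         call. = FALSE)
  }
  fit <- stats::lm(cq ~ log10(copies), data = dilution_series)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope >= 0) {
    stop("invalid assay: standard-curve slope must be negative (Cq falls ",
         "as template rises); got ", format(slope), call. = FALSE)
  }
  efficiency <- 10^(-1 / slope) - 1
  structure(list(slope = slope, intercept = intercept,
                 efficiency = efficiency,
                 efficiency_percent = 100 * efficiency,
                 r_squared = summary(fit)$r.squared,
                 n_levels = length(unique(dilution_series$copies))),
            class = "qpcr_curve")
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.4f * log10(copies) + %.4f\n", x$slope,
    x$intercept))
  cat(sprintf("  efficiency %.2f%%, r^2 %.4f, %d dilution levels\n",
              x$efficiency_percent, x$r_squared, x$n_levels))
  invisible(x)
}

#' Copy number from a Cq value via a standard curve
#'
#' Inverts the fitted line: `copies = 10^((cq - intercept) / slope)`.
#'
#' @param curve A [fit_standard_curve()] object.
#' @param cq Numeric vector of quantification cycles.
#' @return Estimated template copy numbers.
#' @export
quantify_sample <- function(curve, cq) {
  stopifnot(inherits(curve, "qpcr_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Quantify genes by qPCR and normalize to a reference gene
#'
#' Converts one Cq per gene into copy numbers via each gene's own standard
#' curve, expresses them relative to a reference gene (16S rRNA in the
#' assay this reproduces), and reports all pairwise gene ratios — the
#' xoxF5:mxaF comparison being the one of primary interest.
#'
#' @param sample_cq Named numeric vector of Cq values, one per gene.
#' @param curves Named list of [fit_standard_curve()] objects covering
#'   every gene in `sample_cq`, including the reference.
#' @param reference_gene Name of the normalizing gene (e.g. `"16S"`).
#' @return List with `per_gene` (data frame `gene`, `cq`, `copies`,
#'   `ratio_to_reference`) and `pairwise_ratios` (data frame `numerator`,
#'   `denominator`, `ratio` for every ordered gene pair).
#' @export
quantify_and_normalize <- function(sample_cq, curves, reference_gene) {
  genes <- names(sample_cq)
  need <- unique(c(genes, reference_gene))
  missing <- setdiff(need, names(curves))
  if (length(missing) > 0L) {
    stop("no standard curve for gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!reference_gene %in% genes) {
    stop("sample has no Cq for the reference gene '", reference_gene, "'",
         call. = FALSE)
  }
  copies <- vapply(genes, function(g) {
    quantify_sample(curves[[g]], sample_cq[[g]])
  }, numeric(1))
  per_gene <- data.frame(gene = genes, cq = unname(sample_cq[genes]),
                         copies = unname(copies),
                         ratio_to_reference =
                           unname(copies / copies[[reference_gene]]),
                         stringsAsFactors = FALSE)
  pairs <- expand.grid(numerator = genes, denominator = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$numerator != pairs$denominator, , drop = FALSE]
  pairs$ratio <- copies[pairs$numerator] / copies[pairs$denominator]
  rownames(pairs) <- NULL
  list(per_gene = per_gene, pairwise_ratios = pairs)
}
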