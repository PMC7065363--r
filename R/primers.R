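# IUPAC code for each sorted base combination, and the reverse mapping
.iupac_code <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W", "GT" = "K", "AC" = "M",
  "CGT" = "B", "AGT" = "D", "ACT" = "H", "ACG" = "V", "ACGT" = "N")
.iupac_bases <- stats::setNames(names(.iupac_code), .iupac_code)

#' Coerce sequences to an alignment matrix
#'
#' Accepts a character matrix, a named character vector of equal-length
#' aligned sequences, or a `Biostrings::DNAStringSet` /
#' `DNAMultipleAlignment`, and returns an uppercase character matrix with
#' one row per sequence. Allowed characters are `A C G T N -`.
#'
#' @param x Alignment in any of the accepted forms.
#' @return Character matrix with sequence ids as rownames.
#' @export
as_alignment_matrix <- function(x) {
  if (inherits(x, "DNAMultipleAlignment")) {
    x <- methods::as(x, "DNAStringSet")
  }
  if (inherits(x, "DNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.character(x) && !is.matrix(x)) {
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      stop("aligned sequences must have equal length", call. = FALSE)
    }
    ids <- if (is.null(names(x))) sprintf("seq_%d", seq_along(x)) else names(x)
    x <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(x) <- ids
  }
  if (!is.matrix(x)) stop("cannot interpret input as an alignment", call. = FALSE)
  x[] <- toupper(x)
  bad <- setdiff(unique(as.vector(x)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad) > 0L) {
    stop("alignment contains disallowed character(s): ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  if (nrow(x) < 2L) {
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  }
  x
}

#' Per-column conservation profile of an alignment
#'
#' A column is conserved when every sequence carries the same single base
#' from `A/C/G/T`; any gap (`-`) or ambiguity (`N`) anywhere in the column
#' makes it non-conserved.
#'
#' @param alignment Anything accepted by [as_alignment_matrix()].
#' @return Logical vector, one flag per alignment column.
#' @export
conservation_profile <- function(alignment) {
  aln <- as_alignment_matrix(alignment)
  apply(aln, 2L, function(col) {
    u <- unique(col)
    length(u) == 1L && u %in% c("A", "C", "G", "T")
  })
}

#' Window-scan parameters
#'
#' @param min_len,max_len Window length range in nucleotides (default
#'   18-20, the length of a usable primer annealing site).
#' @param max_nonconserved Maximum number of non-conserved columns a window
#'   may contain (default 3); non-conserved columns become degenerate
#'   positions in the consensus primer.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(min_len = 18, max_len = 20, max_nonconserved = 3) {
  if (min_len <= 0 || min_len > max_len) {
    stop("need 0 < min_len <= max_len", call. = FALSE)
  }
  if (max_nonconserved < 0) stop("max_nonconserved must be >= 0", call. = FALSE)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 max_nonconserved = as.integer(max_nonconserved)),
            class = "scan_params")
}

#' Scan an alignment for conserved primer windows
#'
#' Exhaustively enumerates every window of length `min_len`..`max_len`
#' whose non-conserved column count does not exceed `max_nonconserved`.
#' Windows containing any gap or ambiguity column are excluded regardless
#' of the count: a primer cannot span an indel. Candidates are returned in
#' (start, length) order with their degenerate IUPAC consensus; coordinates
#' are 0-based, half-open.
#'
#' @param alignment Anything accepted by [as_alignment_matrix()].
#' @param params A [scan_params()].
#' @return Data frame with columns `start`, `length`, `nonconserved`,
#'   `consensus`, `degeneracy`. Empty (with a warning) when the alignment
#'   is shorter than `min_len`.
#' @examples
#' aln <- simulate_alignment(5, 30, variable_columns = integer(), seed = 1)
#' nrow(scan_conserved_windows(aln)) # 13 + 12 + 11 = 36 windows
#' @export
scan_conserved_windows <- function(alignment, params = scan_params()) {
  stopifnot(inherits(params, "scan_params"))
  aln <- as_alignment_matrix(alignment)
  n_col <- ncol(aln)
  empty <- data.frame(start = integer(), length = integer(),
                      nonconserved = integer(), consensus = character(),
                      degeneracy = integer(), stringsAsFactors = FALSE)
  if (n_col < params$min_len) {
    warning("alignment (", n_col, " columns) is shorter than min_len (",
            params$min_len, "); no windows to scan", call. = FALSE)
    return(empty)
  }
  conserved <- conservation_profile(aln)
  has_gap <- apply(aln, 2L, function(col) any(col %in% c("-", "N")))
  # cumulative sums give O(1) per-window counts over the exhaustive scan
  cum_var <- cumsum(!conserved)
  cum_gap <- cumsum(has_gap)
  count <- function(cum, s, len) cum[s + len] - if (s > 0) cum[s] else 0L

  rows <- list()
  for (start in 0:(n_col - params$min_len)) {
    for (len in params$min_len:params$max_len) {
      if (start + len > n_col) next
      if (count(cum_gap, start, len) > 0) next
      nv <- count(cum_var, start, len)
      if (nv > params$max_nonconserved) next
      cons <- consensus_primer(aln, start, len)
      rows[[length(rows) + 1L]] <- data.frame(
        start = as.integer(start), length = as.integer(len),
        nonconserved = as.integer(nv),
        consensus = cons$consensus, degeneracy = cons$degeneracy,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Degenerate IUPAC consensus over an alignment window
#'
#' Each column is encoded as the minimal IUPAC code covering the bases
#' observed in it; the degeneracy of the primer is the product of the
#' per-column base-set sizes (the number of plain oligos in the mix).
#'
#' @param alignment Anything accepted by [as_alignment_matrix()].
#' @param start 0-based start column of the window.
#' @param length Window length in columns.
#' @return List with elements `consensus` (IUPAC string) and `degeneracy`.
#' @export
consensus_primer <- function(alignment, start, length) {
  aln <- as_alignment_matrix(alignment)
  if (start < 0 || start + length > ncol(aln)) {
    stop("window [", start, ", ", start + length,
         ") falls outside the alignment", call. = FALSE)
  }
  cols <- seq.int(start + 1L, start + length)
  codes <- character(length)
  deg <- 1L
  for (i in seq_along(cols)) {
    bases <- sort(unique(aln[, cols[i]]))
    if (any(bases %in% c("-", "N"))) {
      stop("window contains a gap or ambiguity column at alignment column ",
           cols[i] - 1L, " (0-based); primers cannot span indels",
           call. = FALSE)
    }
    codes[i] <- .iupac_code[[paste(bases, collapse = "")]]
    deg <- deg * length(bases)
  }
  list(consensus = paste(codes, collapse = ""), degeneracy = deg)
}

#' Rank candidate primer windows
#'
#' Convenience sort of a [scan_conserved_windows()] table by increasing
#' (`nonconserved`, `degeneracy`) and decreasing `length`: fewest variable
#' positions first, least degenerate mix first, longer site preferred.
#'
#' @param windows Data frame from [scan_conserved_windows()].
#' @return The same data frame, reordered.
#' @export
rank_windows <- function(windows) {
  windows[order(windows$nonconserved, windows$degeneracy, -windows$length,
                windows$start), , drop = FALSE]
}

# TRUE where the IUPAC primer character covers the template base
.iupac_match <- function(primer_chars, template_chars) {
  sets <- .iupac_bases[primer_chars]
  if (anyNA(sets)) {
    stop("invalid IUPAC character in primer: ",
         paste(unique(primer_chars[is.na(sets)]), collapse = " "),
         call. = FALSE)
  }
  mapply(grepl, template_chars, sets, MoreArgs = list(fixed = TRUE))
}

# mismatch count of a primer at every start position of a plain template;
# positions where the 3'-terminal `exact3` bases mismatch are set to Inf
.scan_primer <- function(primer, template, exact3 = 3L) {
  p <- strsplit(toupper(primer), "")[[1]]
  t <- strsplit(toupper(template), "")[[1]]
  lp <- length(p)
  lt <- length(t)
  if (lt < lp) return(numeric(0))
  n_pos <- lt - lp + 1L
  mm <- numeric(n_pos)
  end_bad <- logical(n_pos)
  tail_idx <- seq.int(max(1L, lp - exact3 + 1L), lp)
  for (s in seq_len(n_pos)) {
    seg <- t[s:(s + lp - 1L)]
    ok <- .iupac_match(p, seg)
    mm[s] <- sum(!ok)
    end_bad[s] <- any(!ok[tail_idx])
  }
  mm[end_bad] <- Inf
  mm
}

.revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
}

#' Predict PCR amplicons of a degenerate primer pair
#'
#' In-silico PCR: the forward primer is scanned along each template's plus
#' strand and the reverse primer along the reverse complement, with
#' IUPAC-aware matching (a degenerate code matches any base it covers). A
#' prediction is emitted for every site pair whose product length falls in
#' `product_range` and whose combined mismatch count is at most
#' `max_mismatches`. Independently of `max_mismatches`, the 3'-terminal
#' `exact_3prime` positions of each primer must match exactly — extension
#' chemistry tolerates no terminal mismatch.
#'
#' @param forward,reverse Primer sequences (IUPAC codes allowed), written
#'   5'->3' as synthesized.
#' @param templates Named character vector or `DNAStringSet` of plain DNA
#'   template sequences.
#' @param max_mismatches Total mismatch allowance across both primers
#'   (default 0).
#' @param product_range Numeric length-2 interval of acceptable product
#'   sizes in bp.
#' @param exact_3prime Number of 3'-terminal positions required to match
#'   exactly (default 3).
#' @return Data frame with columns `template`, `fwd_start` (1-based
#'   plus-strand position), `rev_end` (1-based plus-strand position of the
#'   product's last base), `product_length`, `mismatches`. Zero rows when
#'   nothing amplifies — the negative-control verdict.
#' @export
predict_amplicons <- function(forward, reverse, templates,
                              max_mismatches = 0,
                              product_range = c(100, 3000),
                              exact_3prime = 3L) {
  if (nchar(forward) == 0L || nchar(reverse) == 0L) {
    stop("primers must be non-empty", call. = FALSE)
  }
  if (inherits(templates, "DNAStringSet")) {
    templates <- stats::setNames(as.character(templates), names(templates))
  }
  if (is.null(names(templates))) {
    names(templates) <- sprintf("template_%d", seq_along(templates))
  }
  out <- list()
  for (nm in names(templates)) {
    tmpl <- toupper(templates[[nm]])
    L <- nchar(tmpl)
    fwd_mm <- .scan_primer(forward, tmpl, exact_3prime)
    rev_mm <- .scan_primer(reverse, .revcomp(tmpl), exact_3prime)
    fwd_sites <- which(is.finite(fwd_mm) & fwd_mm <= max_mismatches)
    rev_sites <- which(is.finite(rev_mm) & rev_mm <= max_mismatches)
    lr <- nchar(reverse)
    for (i in fwd_sites) {
      for (j in rev_sites) {
        # reverse site starting at j on the reverse complement ends the
        # product at plus-strand position L - j + 1
        rev_end <- L - j + 1L
        product_length <- rev_end - i + 1L
        if (product_length < nchar(forward) + lr) next
        total_mm <- fwd_mm[i] + rev_mm[j]
        if (total_mm > max_mismatches) next
        if (product_length < product_range[1] ||
            product_length > product_range[2]) next
        out[[length(out) + 1L]] <- data.frame(
          template = nm, fwd_start = i, rev_end = rev_end,
          product_length = product_length, mismatches = total_mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(template = character(), fwd_start = integer(),
                      rev_end = integer(), product_length = integer(),
                      mismatches = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
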