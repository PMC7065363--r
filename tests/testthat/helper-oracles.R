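# Independent brute-force restatements used as oracles. These deliberately
# re-derive results from first principles rather than calling package
# internals.

# literal transcription of the three labelling inequalities
oracle_labelled <- function(a13H, a13L, a12H, a12L, floor, k) {
  floor_ok <- a13H > floor
  c1 <- a13H > a12H
  c2 <- (a13H > k * a13L) && (a12H <= a12L)
  floor_ok && c1 && c2
}

random_profiles <- function(n, seed) {
  set.seed(seed)
  data.frame(
    taxon_id = sprintf("t%d", seq_len(n)),
    # mix of smooth values and exact ties/zeros to probe strictness
    a13H = sample(c(runif(n, 0, 0.2), 0, 0.001))[seq_len(n)],
    a13L = sample(c(runif(n, 0, 0.05), 0, 0.001))[seq_len(n)],
    a12H = sample(c(runif(n, 0, 0.05), 0, 0.001))[seq_len(n)],
    a12L = sample(c(runif(n, 0, 0.05), 0, 0.001))[seq_len(n)],
    stringsAsFactors = FALSE)
}

# naive per-window enumeration of conserved primer windows
oracle_windows <- function(aln, min_len = 18, max_len = 20,
                           max_nonconserved = 3) {
  n_col <- ncol(aln)
  out <- list()
  if (n_col >= min_len) {
    for (start in 0:(n_col - min_len)) {
      for (len in min_len:max_len) {
        if (start + len > n_col) next
        ok <- TRUE
        nv <- 0L
        for (j in (start + 1L):(start + len)) {
          col <- aln[, j]
          if (any(col %in% c("-", "N"))) { ok <- FALSE; break }
          if (length(unique(col)) > 1L) nv <- nv + 1L
        }
        if (ok && nv <= max_nonconserved) {
          out[[length(out) + 1L]] <- c(start = start, length = len,
                                       nonconserved = nv)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), length = integer(),
                      nonconserved = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

random_alignment <- function(n_seqs, n_cols, p_var = 0.15, p_gap = 0.02,
                             seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  aln <- matrix(sample(bases, n_cols, replace = TRUE), nrow = 1)[
    rep(1, n_seqs), , drop = FALSE]
  for (j in seq_len(n_cols)) {
    r <- runif(1)
    if (r < p_gap) {
      aln[sample(n_seqs, 1), j] <- "-"
    } else if (r < p_gap + p_var) {
      rows <- sample(n_seqs, sample(n_seqs - 1, 1))
      aln[rows, j] <- sample(bases, 1)
    }
  }
  rownames(aln) <- sprintf("s%d", seq_len(n_seqs))
  aln
}
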