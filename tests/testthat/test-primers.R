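test_that("conservation profile requires unanimity and rejects gap columns", {
  aln <- rbind(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  expect_true(all(conservation_profile(aln)))

  aln[2, 2] <- "-"
  expect_identical(conservation_profile(aln), c(TRUE, FALSE, TRUE, TRUE))

  aln[2, 2] <- "C"; aln[1, 3] <- "A" # {A,G} column
  expect_identical(conservation_profile(aln), c(TRUE, TRUE, FALSE, TRUE))

  expect_error(as_alignment_matrix(matrix("A", nrow = 1, ncol = 5)),
               "at least 2")
  expect_error(as_alignment_matrix(rbind("AX", "AA")), "disallowed")
})

test_that("fully conserved 30-column alignment yields all 36 windows", {
  aln <- simulate_alignment(5, 30, variable_columns = integer(), seed = 1)
  win <- scan_conserved_windows(aln)
  expect_identical(nrow(win), 36L) # 13 + 12 + 11 start positions
  expect_true(all(win$nonconserved == 0))
  expect_true(all(win$degeneracy == 1))
  # ordered by (start, length)
  expect_identical(order(win$start, win$length), seq_len(36L))
})

test_that("variable columns every 4 positions exclude all 18-20 nt windows", {
  aln <- simulate_alignment(6, 20, variable_columns = c(0, 4, 8, 12, 16),
                            seed = 3)
  expect_identical(nrow(scan_conserved_windows(aln)), 0L)
})

test_that("window scan equals naive enumeration on random gappy alignments", {
  for (i in 1:25) {
    aln <- random_alignment(n_seqs = sample(2:10, 1),
                            n_cols = sample(40:200, 1), seed = 100 + i)
    got <- scan_conserved_windows(aln)
    want <- oracle_windows(aln)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_identical(got$start, want$start)
      expect_identical(got$length, want$length)
      expect_identical(got$nonconserved, want$nonconserved)
    }
  }
})

test_that("relaxing scan parameters never removes windows", {
  aln <- random_alignment(6, 120, p_var = 0.2, seed = 77)
  key <- function(w) paste(w$start, w$length)
  strict <- scan_conserved_windows(aln, scan_params(max_nonconserved = 1))
  loose <- scan_conserved_windows(aln, scan_params(max_nonconserved = 4))
  expect_true(all(key(strict) %in% key(loose)))
  longer_min <- scan_conserved_windows(aln, scan_params(min_len = 19))
  default <- scan_conserved_windows(aln)
  expect_true(all(key(longer_min) %in% key(default)))
})

test_that("short alignments warn and return an empty window table", {
  aln <- simulate_alignment(3, 10, seed = 1)
  expect_warning(win <- scan_conserved_windows(aln), "shorter than")
  expect_identical(nrow(win), 0L)
})

test_that("degenerate consensus uses minimal IUPAC codes with product degeneracy", {
  aln <- rbind(c("A", "A", "C", "A"),
               c("A", "G", "T", "A"),
               c("A", "G", "T", "A"))
  cons <- consensus_primer(aln, start = 0, length = 4)
  expect_identical(cons$consensus, "ARYA")
  expect_identical(cons$degeneracy, 4L) # 1 * 2 * 2 * 1
  # {A,G}, {C,T}, {A,C,G,T} -> 2 * 2 * 4 = 16
  aln2 <- rbind(c("A", "C", "A"), c("G", "T", "C"),
                c("A", "C", "G"), c("G", "T", "T"))
  cons2 <- consensus_primer(aln2, 0, 3)
  expect_identical(cons2$consensus, "RYN")
  expect_identical(cons2$degeneracy, 16L)

  gappy <- rbind(c("A", "-"), c("A", "C"))
  expect_error(consensus_primer(gappy, 0, 2), "gap")
  expect_error(consensus_primer(aln, 2, 4), "outside")
})

test_that("every aligned sequence matches its own window consensus", {
  for (i in 1:10) {
    aln <- random_alignment(5, 80, p_gap = 0, seed = 200 + i)
    win <- scan_conserved_windows(aln)
    if (nrow(win) == 0) next
    w <- win[1, ]
    cons <- strsplit(w$consensus, "")[[1]]
    iupac <- Biostrings::IUPAC_CODE_MAP
    for (r in seq_len(nrow(aln))) {
      seg <- aln[r, (w$start + 1):(w$start + w$length)]
      expect_true(all(mapply(function(b, code) grepl(b, iupac[[code]]),
                             seg, cons)))
    }
  }
})

test_that("in-silico PCR finds the planted ~500 bp amplicon and nothing else", {
  set.seed(6)
  bases <- c("A", "C", "G", "T")
  fwd <- "ATGACCGTTAGGCAGATCC"
  rev <- "TTGCCAGATACCGGTAGCA" # as synthesized, 5'->3'
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  tmpl <- paste(sample(bases, 700, replace = TRUE), collapse = "")
  # forward site at 101; product ends (inclusive of reverse site) at 600
  substr(tmpl, 101, 119) <- fwd
  substr(tmpl, 582, 600) <- revcomp(rev)
  hits <- predict_amplicons(fwd, rev, c(positive = tmpl),
                            product_range = c(300, 800))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$fwd_start, 101L)
  expect_identical(hits$product_length, 500L)
  expect_identical(hits$mismatches, 0)

  # negative control: no reverse-complement site, no product
  neg <- paste(sample(bases, 700, replace = TRUE), collapse = "")
  substr(neg, 101, 119) <- fwd
  expect_identical(nrow(predict_amplicons(fwd, rev, c(n = neg))), 0L)

  expect_error(predict_amplicons("ATGZ", rev, c(t = tmpl)), "IUPAC")
})

test_that("degenerate primer codes match the bases they cover", {
  tmpl <- paste0(strrep("C", 60), "ATGACCGTTAGGCAGATCC", strrep("C", 400),
                 "TGCTACCGGTATCTGGCAA", strrep("C", 60))
  # R in the forward primer covers the template G at that position
  fwd_deg <- "ATGACCGTTARGCAGATCC"
  hits <- predict_amplicons(fwd_deg, "TTGCCAGATACCGGTAGCA", c(t = tmpl),
                            product_range = c(100, 600))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$mismatches, 0)

  # a 3'-terminal mismatch kills the site even with a mismatch allowance
  fwd_bad3 <- "ATGACCGTTAGGCAGATCA"
  expect_identical(nrow(predict_amplicons(fwd_bad3, "TTGCCAGATACCGGTAGCA",
                                          c(t = tmpl), max_mismatches = 2,
                                          product_range = c(100, 600))), 0L)
  # the same mismatch away from the 3' end is tolerated by the allowance
  fwd_bad5 <- "TTGACCGTTAGGCAGATCC"
  expect_identical(nrow(predict_amplicons(fwd_bad5, "TTGCCAGATACCGGTAGCA",
                                          c(t = tmpl), max_mismatches = 2,
                                          product_range = c(100, 600))), 1L)
})

test_that("primers from conserved windows amplify intact templates only", {
  aln <- simulate_alignment(5, 600, variable_columns = c(30, 250, 460),
                            seed = 21)
  win <- rank_windows(scan_conserved_windows(aln))
  expect_gt(nrow(win), 0)
  fwd_w <- win[win$start < 100, ][1, ]
  rev_w <- win[win$start > 450, ][1, ]
  fwd <- consensus_primer(aln, fwd_w$start, fwd_w$length)$consensus
  rev_plus <- consensus_primer(aln, rev_w$start, rev_w$length)$consensus
  rc <- function(x) chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  templates <- c(intact = paste(aln[1, ], collapse = ""))
  # disrupted negative control: reverse the primer windows in the template
  disrupted <- aln[1, ]
  idx <- (fwd_w$start + 1):(fwd_w$start + fwd_w$length)
  disrupted[idx] <- rev(chartr("ACGT", "TGCA", disrupted[idx]))
  idx2 <- (rev_w$start + 1):(rev_w$start + rev_w$length)
  disrupted[idx2] <- rev(chartr("ACGT", "TGCA", disrupted[idx2]))
  templates["disrupted"] <- paste(disrupted, collapse = "")
  hits <- predict_amplicons(fwd, rc(rev_plus), templates,
                            product_range = c(200, 600))
  expect_true("intact" %in% hits$template)
  expect_false("disrupted" %in% hits$template)
})
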