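#' Configuration for a synthetic SIP experiment
#'
#' Builds and validates the parameter set for [simulate_experiment()]. The
#' defaults describe a soil-like community of 200 taxa in which 20 taxa are
#' primary consumers of the 13C substrate, 5 are cross-feeders assimilating
#' the label second-hand, and 5 are autotrophs that fix 13CO2 regardless of
#' plant presence. Enrichment of labelled DNA in the heavy fraction is
#' multiplicative and log-normal: a labelled taxon's heavy-fraction weight is
#' its baseline abundance times a factor drawn with log-mean
#' `log(enrichment_mean)` and log-sd `enrichment_sd`. Unlabelled DNA still
#' appears in heavy fractions at rate `background_leakage` (e.g. GC-rich
#' genomes banding high).
#'
#' @param n_taxa Number of taxa in the community.
#' @param n_labelled Number of truly 13C-labelled (primary consumer) taxa.
#' @param n_crossfeeders Number of cross-feeding taxa, enriched by the weaker
#'   `crossfeed_enrichment_mean` law.
#' @param n_autotrophs Number of autotrophic taxa, enriched in 13C heavy
#'   fractions of both planted and unplanted treatments (the confounder that
#'   unplanted-control exclusion removes).
#' @param base_abundance_concentration Concentration of the symmetric
#'   Dirichlet from which the baseline composition is drawn; values below 1
#'   give the uneven, few-dominant-taxa profiles typical of soil.
#' @param enrichment_mean,enrichment_sd Log-normal law for the heavy-fraction
#'   enrichment factor of labelled (and autotrophic) taxa; `enrichment_mean`
#'   is the median factor, `enrichment_sd` the log-scale spread.
#' @param crossfeed_enrichment_mean Median enrichment factor for
#'   cross-feeders; must be positive and is expected to lie below
#'   `enrichment_mean`.
#' @param background_leakage Fraction in `[0, 1]` of an unlabelled taxon's
#'   baseline abundance that leaks into heavy fractions.
#' @param read_depth Multinomial read depth per fraction sample.
#' @param n_replicates Number of replicate incubations per treatment/isotope.
#' @param seed Integer seed governing all draws.
#' @return An object of class `sip_sim_config` (a validated list).
#' @seealso [simulate_experiment()]
#' @export
sip_sim_config <- function(n_taxa = 200,
                           n_labelled = 20,
                           n_crossfeeders = 5,
                           n_autotrophs = 5,
                           base_abundance_concentration = 1,
                           enrichment_mean = 50,
                           enrichment_sd = 0.25,
                           crossfeed_enrichment_mean = 5,
                           background_leakage = 0.1,
                           read_depth = 20000,
                           n_replicates = 3,
                           seed = 1L) {
  cfg <- list(
    n_taxa = as.integer(n_taxa),
    n_labelled = as.integer(n_labelled),
    n_crossfeeders = as.integer(n_crossfeeders),
    n_autotrophs = as.integer(n_autotrophs),
    base_abundance_concentration = base_abundance_concentration,
    enrichment_mean = enrichment_mean,
    enrichment_sd = enrichment_sd,
    crossfeed_enrichment_mean = crossfeed_enrichment_mean,
    background_leakage = background_leakage,
    read_depth = as.integer(read_depth),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sip_sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid simulation configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  counts <- c("n_taxa", "n_labelled", "n_crossfeeders", "n_autotrophs",
              "read_depth", "n_replicates")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0L) bad(f, "must be a non-negative count")
  }
  if (cfg$n_taxa < 1L) bad("n_taxa", "must be at least 1")
  if (cfg$read_depth < 1L) bad("read_depth", "must be at least 1")
  if (cfg$n_replicates < 1L) bad("n_replicates", "must be at least 1")
  for (f in c("base_abundance_concentration", "enrichment_mean",
              "enrichment_sd", "crossfeed_enrichment_mean")) {
    v <- cfg[[f]]
    if (length(v) != 1L || !is.finite(v) || v <= 0) bad(f, "must be strictly positive")
  }
  v <- cfg$background_leakage
  if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
    bad("background_leakage", "must lie in [0, 1]")
  }
  if (cfg$n_labelled + cfg$n_crossfeeders + cfg$n_autotrophs > cfg$n_taxa) {
    bad("n_labelled", paste0(
      "+ n_crossfeeders + n_autotrophs exceeds n_taxa (",
      cfg$n_labelled + cfg$n_crossfeeders + cfg$n_autotrophs, " > ",
      cfg$n_taxa, ")"))
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed)) bad("seed", "must be an integer")
  invisible(cfg)
}

#' Simulate a fraction-resolved SIP experiment with known truth
#'
#' Generates relative-abundance tables for every combination of treatment
#' (`rhizosphere`, `unplanted`), isotope (`13C`, `12C`), fraction class
#' (`heavy`, `light`) and replicate, together with a truth table recording
#' each taxon's status. The baseline composition is drawn once per treatment
#' from a symmetric Dirichlet. In a 13C incubation the heavy-fraction weight
#' of an isotope-assimilating taxon i is `baseline_i * e_i`, with `e_i`
#' drawn from the labelled enrichment law for primary consumers
#' (rhizosphere only), the cross-feeder law for cross-feeders (rhizosphere
#' only), and the labelled law for autotrophs in *both* treatments; its
#' light-fraction weight is depleted to `baseline_i / e_i`, since DNA that
#' banded heavy has left the light fraction. Every other taxon contributes
#' `lambda_i * baseline_i` to heavy fractions and `baseline_i` to light
#' fractions, where `lambda_i` is a taxon-specific leakage rate: a random
#' 5% minority of "high-GC" taxa leak at `min(1, 20 * background_leakage)`
#' and dominate the otherwise DNA-poor heavy fractions of 12C controls,
#' the rest at `background_leakage` — mirroring the GC-driven density
#' overlap that makes the 12C-heavy control informative. 12C incubations
#' receive leakage only. Weights are closed to compositions, counts drawn
#' multinomially at `read_depth` per sample and re-closed. Replicates share
#' the baseline, truth and leakage but redraw enrichment factors and
#' sampling noise.
#'
#' @param config A [sip_sim_config()] object.
#' @param timepoint Timepoint label written to the sample sheet.
#' @return An object of class `sip_experiment`: a list with elements
#'   `abundance` (taxa x samples matrix of relative abundances, columns sum
#'   to 1), `samples` (sample sheet data frame with columns `sample_id`,
#'   `treatment`, `isotope`, `fraction_class`, `replicate`, `timepoint`),
#'   `truth` (data frame `taxon_id`, `status`) and `config`.
#' @examples
#' ex <- simulate_experiment(sip_sim_config(n_taxa = 50, seed = 7))
#' table(ex$truth$status)
#' @export
simulate_experiment <- function(config = sip_sim_config(), timepoint = "T1") {
  stopifnot(inherits(config, "sip_sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  taxa <- sprintf("taxon_%03d", seq_len(config$n_taxa))
  status <- rep("unlabelled", config$n_taxa)
  idx_lab <- seq_len(config$n_labelled)
  idx_cf <- seq_len(config$n_crossfeeders) + config$n_labelled
  idx_auto <- seq_len(config$n_autotrophs) + config$n_labelled + config$n_crossfeeders
  status[idx_lab] <- "labelled"
  status[idx_cf] <- "crossfeeder"
  status[idx_auto] <- "autotroph"
  truth <- data.frame(taxon_id = taxa, status = status,
                      stringsAsFactors = FALSE)

  # taxon-specific heavy-fraction leakage: a high-GC minority bands close
  # to labelled DNA and dominates 12C-heavy fractions
  high_gc <- stats::runif(config$n_taxa) < 0.05
  lambda <- ifelse(high_gc, min(1, 20 * config$background_leakage),
                   config$background_leakage)

  treatments <- c("rhizosphere", "unplanted")
  isotopes <- c("13C", "12C")
  classes <- c("heavy", "light")
  n_samples <- length(treatments) * length(isotopes) * length(classes) *
    config$n_replicates
  abundance <- matrix(0, nrow = config$n_taxa, ncol = n_samples,
                      dimnames = list(taxa, NULL))
  sheet <- vector("list", n_samples)
  col <- 0L

  for (treatment in treatments) {
    baseline <- stats::rgamma(config$n_taxa,
                              shape = config$base_abundance_concentration)
    baseline <- baseline / sum(baseline)
    for (isotope in isotopes) {
      for (rep_i in seq_len(config$n_replicates)) {
        e <- rep(1, config$n_taxa)
        enriched <- rep(FALSE, config$n_taxa)
        if (isotope == "13C") {
          if (treatment == "rhizosphere") {
            e[idx_lab] <- stats::rlnorm(length(idx_lab),
                                        meanlog = log(config$enrichment_mean),
                                        sdlog = config$enrichment_sd)
            e[idx_cf] <- stats::rlnorm(length(idx_cf),
                                       meanlog = log(config$crossfeed_enrichment_mean),
                                       sdlog = config$enrichment_sd)
            enriched[c(idx_lab, idx_cf)] <- TRUE
          }
          e[idx_auto] <- stats::rlnorm(length(idx_auto),
                                       meanlog = log(config$enrichment_mean),
                                       sdlog = config$enrichment_sd)
          enriched[idx_auto] <- TRUE
        }
        heavy_w <- ifelse(enriched, baseline * e, baseline * lambda)
        light_w <- ifelse(enriched, baseline / e, baseline)
        for (fraction_class in classes) {
          w <- if (fraction_class == "heavy") heavy_w else light_w
          if (sum(w) <= 0) w <- rep(1, config$n_taxa)
          counts <- stats::rmultinom(1L, size = config$read_depth,
                                     prob = w / sum(w))[, 1L]
          col <- col + 1L
          abundance[, col] <- counts / config$read_depth
          sheet[[col]] <- data.frame(
            sample_id = sprintf("%s_%s_%s_r%d", treatment, isotope,
                                fraction_class, rep_i),
            treatment = treatment, isotope = isotope,
            fraction_class = fraction_class, replicate = rep_i,
            timepoint = timepoint, stringsAsFactors = FALSE)
        }
      }
    }
  }
  samples <- do.call(rbind, sheet)
  colnames(abundance) <- samples$sample_id
  structure(list(abundance = abundance, samples = samples, truth = truth,
                 config = config),
            class = "sip_experiment")
}

#' @export
print.sip_experiment <- function(x, ...) {
  cat("Synthetic SIP experiment:", nrow(x$abundance), "taxa x",
      ncol(x$abundance), "fraction samples\n")
  cat("Truth:", paste(sprintf("%s=%d", names(table(x$truth$status)),
                              as.integer(table(x$truth$status))),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a DNA multiple alignment with planted variable columns
#'
#' Produces an equal-length, gap-free alignment in which every column not in
#' `variable_columns` carries one identical base across sequences, and every
#' listed column is forced to contain at least two distinct bases. Used to
#' build fixtures with known conserved windows for the primer-design scan.
#'
#' @param n_seqs Number of sequences (at least 2).
#' @param n_cols Alignment length in columns.
#' @param variable_columns Integer vector of 0-based column indices to make
#'   variable; empty for a fully conserved alignment.
#' @param seed Integer seed.
#' @return A character matrix (`n_seqs` x `n_cols`) of bases, rownames
#'   `seq_1`, `seq_2`, ...
#' @export
simulate_alignment <- function(n_seqs, n_cols, variable_columns = integer(),
                               seed = 1L) {
  if (n_seqs < 2L) {
    stop("n_seqs must be at least 2: conservation is undefined for a single sequence",
         call. = FALSE)
  }
  variable_columns <- as.integer(variable_columns)
  if (any(variable_columns < 0L | variable_columns >= n_cols)) {
    stop("variable_columns indices must lie in [0, n_cols)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  consensus <- sample(bases, n_cols, replace = TRUE)
  aln <- matrix(rep(consensus, each = n_seqs), nrow = n_seqs,
                dimnames = list(sprintf("seq_%d", seq_len(n_seqs)), NULL))
  for (j in variable_columns + 1L) {
    # force >= 2 distinct bases: flip a random non-empty proper subset of rows
    n_flip <- sample(seq_len(n_seqs - 1L), 1L)
    rows <- sample(seq_len(n_seqs), n_flip)
    alt <- sample(setdiff(bases, consensus[j]), 1L)
    aln[rows, j] <- alt
  }
  aln
}

#' Simulate a metagenome gene-hit table
#'
#' Expected hit count for clade c is proportional to
#' `true_abundance_c * length_c`, scaled so the expectations sum to
#' `total_reads`; counts are Poisson-distributed around the expectation
#' unless `noise = FALSE`, in which case the exact expectations are
#' returned. Length/read normalization of the output recovers
#' `true_abundances` up to a common factor.
#'
#' @param clades Character vector of clade names.
#' @param lengths_bp Positive reference gene lengths (bp), same length.
#' @param true_abundances Non-negative true abundances, same length.
#' @param total_reads Total expected hit count across clades.
#' @param seed Integer seed (ignored when `noise = FALSE`).
#' @param noise Draw Poisson counts (`TRUE`, default) or return exact
#'   expectations (`FALSE`).
#' @return Data frame with columns `clade`, `length_bp`, `hit_count`.
#' @export
simulate_gene_hits <- function(clades, lengths_bp, true_abundances,
                               total_reads, seed = 1L, noise = TRUE) {
  n <- length(clades)
  if (length(lengths_bp) != n || length(true_abundances) != n) {
    stop("clades, lengths_bp and true_abundances must have equal length",
         call. = FALSE)
  }
  if (any(lengths_bp <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(true_abundances < 0)) stop("abundances must be non-negative", call. = FALSE)
  w <- true_abundances * lengths_bp
  expected <- if (sum(w) > 0) total_reads * w / sum(w) else rep(0, n)
  hits <- if (noise) {
    set.seed(as.integer(seed))
    stats::rpois(n, expected)
  } else {
    expected
  }
  data.frame(clade = clades, length_bp = lengths_bp, hit_count = hits,
             stringsAsFactors = FALSE)
}
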