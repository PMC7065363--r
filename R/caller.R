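#' Parameters of the 13C-labelling decision rule
#'
#' @param floor Relative-abundance floor a taxon's 13C-heavy abundance must
#'   strictly exceed to be considered at all (default 0.001, i.e. 0.1%).
#' @param k Enrichment factor: the 13C-heavy abundance must strictly exceed
#'   `k` times the 13C-light abundance. Use `k = 10` for substrate-based
#'   labelling such as methanol SIP (cross-feeding guard) and `k = 2` for
#'   the more transient 13CO2 labelling.
#' @return An object of class `call_params`.
#' @export
call_params <- function(floor = 0.001, k = 10) {
  if (length(floor) != 1L || !is.finite(floor) || floor < 0 || floor >= 1) {
    stop("floor must lie in [0, 1)", call. = FALSE)
  }
  if (length(k) != 1L || !is.finite(k) || k < 1) {
    stop("k must be >= 1", call. = FALSE)
  }
  structure(list(floor = floor, k = k), class = "call_params")
}

#' Build a fraction profile table
#'
#' A fraction profile records, per taxon, the relative abundance in the four
#' fraction classes of a SIP experiment: 13C-heavy (`a13H`), 13C-light
#' (`a13L`), 12C-heavy (`a12H`) and 12C-light (`a12L`).
#'
#' @param taxon_id Character vector of taxon identifiers.
#' @param a13H,a13L,a12H,a12L Relative abundances in `[0, 1]`, recycled to
#'   the length of `taxon_id`.
#' @return Data frame of class `fraction_profile`.
#' @export
fraction_profile <- function(taxon_id, a13H, a13L, a12H, a12L) {
  df <- data.frame(taxon_id = as.character(taxon_id),
                   a13H = a13H, a13L = a13L, a12H = a12H, a12L = a12L,
                   stringsAsFactors = FALSE)
  vals <- as.matrix(df[, c("a13H", "a13L", "a12H", "a12L")])
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("fraction abundances must lie in [0, 1]", call. = FALSE)
  }
  class(df) <- c("fraction_profile", "data.frame")
  df
}

#' Average replicate fraction profiles for one taxon
#'
#' Replicate incubations are combined by the arithmetic mean of each of the
#' four fraction abundances before the labelling criteria are applied. A
#' taxon absent from a replicate contributes 0 for that replicate, so
#' supply one row per replicate with explicit zeros (as
#' [call_experiment()] does internally).
#'
#' @param replicates A `fraction_profile` data frame whose rows are
#'   replicates of a single taxon.
#' @return A one-row `fraction_profile`.
#' @export
mean_profile <- function(replicates) {
  if (nrow(replicates) == 0L) {
    stop("cannot average an empty set of replicate profiles", call. = FALSE)
  }
  ids <- unique(replicates$taxon_id)
  if (length(ids) != 1L) {
    stop("mean_profile expects replicates of a single taxon, got: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  fraction_profile(ids,
                   mean(replicates$a13H), mean(replicates$a13L),
                   mean(replicates$a12H), mean(replicates$a12L))
}

#' Apply the 13C-labelling criteria to fraction profiles
#'
#' A taxon is called 13C labelled when all three conditions hold on its
#' (replicate-averaged) profile:
#' \enumerate{
#'   \item abundance floor: `a13H > floor` (strict);
#'   \item criterion 1: `a13H > a12H` (strict) — more abundant in the
#'     13C-heavy than the 12C-heavy fraction;
#'   \item criterion 2: `a13H > k * a13L` (strict) *and* `a12H <= a12L`
#'     (non-strict) — k-fold heavy/light enrichment under 13C but not under
#'     12C.
#' }
#' The strictness of each inequality follows the rule as stated: all `>`
#' comparisons are strict, the `a12H <= a12L` comparison is not. Note that
#' `a13L = 0` with `a13H > 0` passes the k test for any `k`.
#'
#' @param profile A `fraction_profile` data frame (one row per taxon).
#' @param params A [call_params()].
#' @return Data frame of class `label_call` with columns `taxon_id`,
#'   the four abundances, logical flags `passes_floor`, `criterion1`,
#'   `criterion2`, `labelled`, and `final_status` in
#'   `{"labelled", "not_labelled", "below_floor"}` (the fourth status,
#'   `"excluded_control"`, is assigned by [apply_control_exclusion()]).
#' @examples
#' p <- fraction_profile("t1", a13H = 0.05, a13L = 0.004,
#'                       a12H = 0.0005, a12L = 0.001)
#' call_taxon(p, call_params(k = 10))
#' @export
call_taxon <- function(profile, params = call_params()) {
  stopifnot(inherits(params, "call_params"))
  passes_floor <- profile$a13H > params$floor
  criterion1 <- profile$a13H > profile$a12H
  criterion2 <- (profile$a13H > params$k * profile$a13L) &
    (profile$a12H <= profile$a12L)
  labelled <- passes_floor & criterion1 & criterion2
  final_status <- ifelse(!passes_floor, "below_floor",
                         ifelse(labelled, "labelled", "not_labelled"))
  out <- data.frame(taxon_id = profile$taxon_id,
                    a13H = profile$a13H, a13L = profile$a13L,
                    a12H = profile$a12H, a12L = profile$a12L,
                    passes_floor = passes_floor,
                    criterion1 = criterion1,
                    criterion2 = criterion2,
                    labelled = labelled,
                    final_status = final_status,
                    stringsAsFactors = FALSE)
  class(out) <- c("label_call", "data.frame")
  out
}

#' Exclude taxa labelled in the unplanted control
#'
#' Autotrophs fixing 13CO2 become labelled regardless of plant presence;
#' incubating unplanted soil under the same atmosphere exposes them. Any
#' taxon called labelled in *both* the test and the control group has its
#' test `final_status` set to `"excluded_control"`. All other rows are
#' untouched and input order is preserved; both call tables should have
#' been computed with the same parameters.
#'
#' @param test_calls,control_calls `label_call` data frames.
#' @return `test_calls` with control-labelled taxa excluded.
#' @export
apply_control_exclusion <- function(test_calls, control_calls) {
  control_labelled <- control_calls$taxon_id[
    control_calls$final_status == "labelled"]
  hit <- test_calls$final_status == "labelled" &
    test_calls$taxon_id %in% control_labelled
  test_calls$final_status[hit] <- "excluded_control"
  test_calls
}

# replicate-aware class mean: average samples of one class within each
# replicate, then average the replicate means (robust to unequal sample
# counts per replicate)
.class_mean <- function(abundance, samples, iso, cls) {
  sel <- samples$isotope == iso & samples$fraction_class == cls
  if (!any(sel)) return(NULL)
  sub <- samples[sel, , drop = FALSE]
  per_rep <- vapply(split(sub$sample_id, sub$replicate), function(ids) {
    rowMeans(abundance[, ids, drop = FALSE])
  }, numeric(nrow(abundance)))
  rowMeans(as.matrix(per_rep))
}

# per-replicate profile matrix for the floor-per-replicate switch
.replicate_values <- function(abundance, samples, iso, cls) {
  sel <- samples$isotope == iso & samples$fraction_class == cls
  sub <- samples[sel, , drop = FALSE]
  vapply(split(sub$sample_id, sub$replicate), function(ids) {
    rowMeans(abundance[, ids, drop = FALSE])
  }, numeric(nrow(abundance)))
}

#' Call 13C-labelled taxa for a whole experiment
#'
#' Orchestrates the full decision procedure on an abundance matrix plus
#' sample sheet: builds replicate-averaged fraction profiles per taxon,
#' treatment and timepoint, applies [call_taxon()], and — when
#' `control_treatment` is given — applies [apply_control_exclusion()] to
#' every other treatment using the control's calls at the same timepoint
#' and parameters. Criteria are applied independently per timepoint.
#'
#' @param abundance Taxa x samples numeric matrix of relative abundances
#'   (taxa as rownames, sample ids as colnames), or a `sip_experiment`
#'   object from [simulate_experiment()].
#' @param samples Sample sheet data frame with columns `sample_id`,
#'   `treatment`, `isotope` (`"13C"`/`"12C"`), `fraction_class`
#'   (`"heavy"`/`"light"`), `replicate` and optionally `timepoint`;
#'   ignored when `abundance` is a `sip_experiment`.
#' @param params A [call_params()].
#' @param control_treatment Treatment name whose labelled taxa are excluded
#'   from all other treatments (e.g. `"unplanted"`), or `NULL` for no
#'   exclusion.
#' @param floor_per_replicate If `TRUE`, the abundance floor must be
#'   exceeded by `a13H` in every replicate individually rather than by the
#'   replicate mean (default `FALSE`: floor applied after averaging).
#' @param mode `"average"` (default) averages replicates into one profile
#'   before calling; `"vote"` calls each replicate separately and requires
#'   a strict majority of replicates to be labelled (reported abundances
#'   are still the replicate means).
#' @return A `label_call` data frame with additional `treatment` and
#'   `timepoint` columns, one row per taxon/treatment/timepoint.
#' @export
call_experiment <- function(abundance, samples = NULL,
                            params = call_params(),
                            control_treatment = NULL,
                            floor_per_replicate = FALSE,
                            mode = c("average", "vote")) {
  mode <- match.arg(mode)
  if (inherits(abundance, "sip_experiment")) {
    samples <- abundance$samples
    abundance <- abundance$abundance
  }
  if (is.null(samples)) stop("a sample sheet is required", call. = FALSE)
  samples <- validate_sample_sheet(samples)
  unknown <- setdiff(colnames(abundance), samples$sample_id)
  if (length(unknown) > 0L) {
    stop("abundance table contains sample(s) missing from the sample sheet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  samples <- samples[samples$sample_id %in% colnames(abundance), , drop = FALSE]

  results <- list()
  for (tp in unique(samples$timepoint)) {
    for (trt in unique(samples$treatment)) {
      sub <- samples[samples$timepoint == tp & samples$treatment == trt, ,
                     drop = FALSE]
      classes <- list(a13H = c("13C", "heavy"), a13L = c("13C", "light"),
                      a12H = c("12C", "heavy"), a12L = c("12C", "light"))
      means <- lapply(classes, function(cl) {
        .class_mean(abundance, sub, cl[1], cl[2])
      })
      missing <- names(means)[vapply(means, is.null, logical(1))]
      if (length(missing) > 0L) {
        miss <- vapply(classes[missing], function(cl) {
          paste0(cl[1], "-", cl[2])
        }, character(1))
        stop("treatment '", trt, "' (timepoint '", tp,
             "') has no sample for fraction class(es): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      prof <- fraction_profile(rownames(abundance), means$a13H, means$a13L,
                               means$a12H, means$a12L)
      calls <- call_taxon(prof, params)
      if (mode == "vote") {
        reps <- lapply(classes, function(cl) {
          .replicate_values(abundance, sub, cl[1], cl[2])
        })
        n_rep <- ncol(reps$a13H)
        votes <- matrix(FALSE, nrow(abundance), n_rep)
        for (r in seq_len(n_rep)) {
          rp <- fraction_profile(rownames(abundance), reps$a13H[, r],
                                 reps$a13L[, r], reps$a12H[, r],
                                 reps$a12L[, r])
          votes[, r] <- call_taxon(rp, params)$labelled
        }
        calls$labelled <- rowSums(votes) > n_rep / 2
        calls$final_status <- ifelse(!calls$passes_floor, "below_floor",
                                     ifelse(calls$labelled, "labelled",
                                            "not_labelled"))
      }
      if (floor_per_replicate) {
        rep13H <- .replicate_values(abundance, sub, "13C", "heavy")
        strict_floor <- apply(rep13H > params$floor, 1L, all)
        demote <- calls$passes_floor & !strict_floor
        calls$passes_floor <- strict_floor
        calls$labelled[demote] <- FALSE
        calls$final_status[demote] <- "below_floor"
      }
      calls$treatment <- trt
      calls$timepoint <- tp
      results[[paste(tp, trt, sep = "/")]] <- calls
    }
  }

  if (!is.null(control_treatment)) {
    trts <- unique(samples$treatment)
    if (!control_treatment %in% trts) {
      stop("control treatment '", control_treatment,
           "' not present in the sample sheet", call. = FALSE)
    }
    for (tp in unique(samples$timepoint)) {
      ctrl <- results[[paste(tp, control_treatment, sep = "/")]]
      for (trt in setdiff(trts, control_treatment)) {
        key <- paste(tp, trt, sep = "/")
        results[[key]] <- apply_control_exclusion(results[[key]], ctrl)
      }
    }
  }

  out <- do.call(rbind, results)
  rownames(out) <- NULL
  class(out) <- c("label_call", "data.frame")
  out
}

#' Score calls against a simulation truth table
#'
#' @param calls A `label_call` data frame (optionally filtered to one
#'   treatment/timepoint).
#' @param truth Truth table data frame (`taxon_id`, `status`) from
#'   [simulate_experiment()].
#' @param positive_status Truth status counted as a true positive
#'   (default `"labelled"`).
#' @return List with `sensitivity` (labelled taxa recovered),
#'   `specificity` (non-labelled taxa not called), `n_called`, and the
#'   per-status call-rate table.
#' @export
evaluate_calls <- function(calls, truth, positive_status = "labelled") {
  called <- calls$taxon_id[calls$final_status == "labelled"]
  pos <- truth$taxon_id[truth$status == positive_status]
  neg <- truth$taxon_id[truth$status != positive_status]
  rate <- vapply(split(truth$taxon_id, truth$status), function(ids) {
    mean(ids %in% called)
  }, numeric(1))
  list(sensitivity = if (length(pos)) mean(pos %in% called) else NA_real_,
       specificity = if (length(neg)) mean(!neg %in% called) else NA_real_,
       n_called = length(called),
       call_rate_by_status = rate)
}
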