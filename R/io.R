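# All tables are TSV: tab-delimited, UTF-8, '.' decimal — taxon names may
# contain commas, so CSV is deliberately avoided.

#' Read a taxa x samples relative-abundance table
#'
#' Expects a TSV whose header row holds sample ids and whose first column
#' holds taxon ids. Blank cells become 0; any other non-numeric cell is an
#' error reporting its row and column.
#'
#' @param path Path to the TSV file.
#' @param relative Validate values in `[0, 1]` (default TRUE).
#' @return Numeric matrix with taxon rownames and sample colnames.
#' @export
read_abundance_table <- function(path, relative = TRUE) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("abundance table has no sample columns", call. = FALSE)
  taxa <- raw[[1]]
  dup <- unique(taxa[duplicated(taxa)])
  if (length(dup) > 0L) {
    stop("duplicate taxon id(s) in abundance table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells == "" | is.na(cells)] <- "0"
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric cell in abundance table at taxon '",
         taxa[bad[1, 1]], "' (row ", bad[1, 1], "), sample '",
         colnames(cells)[bad[1, 2]], "' (column ", bad[1, 2] + 1L, ")",
         call. = FALSE)
  }
  if (relative && (any(values < 0) || any(values > 1))) {
    stop("relative abundances must lie in [0, 1]", call. = FALSE)
  }
  dimnames(values) <- list(taxa, colnames(cells))
  values
}

#' Write a taxa x samples abundance table as TSV
#'
#' @param abundance Numeric matrix with taxon rownames.
#' @param path Output path.
#' @export
write_abundance_table <- function(abundance, path) {
  df <- data.frame(taxon_id = rownames(abundance), abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate (and default-fill) a SIP sample sheet
#'
#' @param samples Data frame with columns `sample_id`, `treatment`,
#'   `isotope`, `fraction_class`, `replicate`; `timepoint` is added as
#'   `"T1"` when absent.
#' @return The validated sample sheet.
#' @export
validate_sample_sheet <- function(samples) {
  required <- c("sample_id", "treatment", "isotope", "fraction_class",
                "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0L) {
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample sheet contains duplicate sample_id(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_iso <- setdiff(unique(samples$isotope), c("13C", "12C"))
  if (length(bad_iso) > 0L) {
    stop("isotope must be '13C' or '12C'; got: ",
         paste(bad_iso, collapse = ", "), call. = FALSE)
  }
  bad_cls <- setdiff(unique(samples$fraction_class), c("heavy", "light"))
  if (length(bad_cls) > 0L) {
    stop("fraction_class must be 'heavy' or 'light'; got: ",
         paste(bad_cls, collapse = ", "), call. = FALSE)
  }
  if (!"timepoint" %in% names(samples)) samples$timepoint <- "T1"
  samples
}

#' Read a sample sheet TSV
#' @param path Path to the TSV file.
#' @return Validated sample sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write any result table as TSV
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-hit table TSV (columns clade, length_bp, hit_count)
#' @param path Path to the TSV file.
#' @return Data frame.
#' @export
read_gene_hits <- function(path) {
  hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("clade", "length_bp", "hit_count")
  missing <- setdiff(need, names(hits))
  if (length(missing) > 0L) {
    stop("gene-hit table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hits
}

#' Read an aligned FASTA file into an alignment matrix
#' @param path Path to the aligned FASTA.
#' @return Character matrix as from [as_alignment_matrix()].
#' @export
read_alignment <- function(path) {
  as_alignment_matrix(Biostrings::readDNAStringSet(path))
}

#' Write an alignment matrix as aligned FASTA
#' @param alignment Anything accepted by [as_alignment_matrix()].
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  aln <- as_alignment_matrix(alignment)
  seqs <- Biostrings::DNAStringSet(apply(aln, 1L, paste, collapse = ""))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a simulated experiment to disk
#'
#' Emits the abundance table, sample sheet and truth table as TSV files in
#' `dir`, the plain-text exchange format of the pipeline.
#'
#' @param experiment A `sip_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "sip_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    abundance = file.path(dir, "abundance.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_abundance_table(experiment$abundance, paths$abundance)
  write_tsv(experiment$samples, paths$samples)
  write_tsv(experiment$truth, paths$truth)
  paths
}

#' Read and validate a pipeline run configuration
#'
#' The run configuration is a YAML file (or an equivalent list) with a
#' required `caller` section (`k`, `floor`, optional `control_treatment`)
#' and optional `simulation` (passed to [sip_sim_config()]), `input`
#' (`abundance`, `samples` TSV paths), `fractions` (metadata TSV plus
#' calibration/threshold overrides) and `output_dir` entries.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Validated configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("run configuration must be a list or a YAML path",
                             call. = FALSE)
  if (is.null(config$caller)) {
    stop("run configuration error: missing section 'caller'", call. = FALSE)
  }
  for (field in c("k", "floor")) {
    if (is.null(config$caller[[field]])) {
      stop("run configuration error: missing field '", field,
           "' in section 'caller'", call. = FALSE)
    }
  }
  # constructor side effects double as schema validation with named errors
  call_params(floor = config$caller$floor, k = config$caller$k)
  if (!is.null(config$simulation)) {
    do.call(sip_sim_config, config$simulation)
  }
  if (is.null(config$simulation) && is.null(config$input)) {
    stop("run configuration error: provide either 'simulation' or 'input'",
         call. = FALSE)
  }
  if (!is.null(config$input)) {
    for (field in c("abundance", "samples")) {
      if (is.null(config$input[[field]])) {
        stop("run configuration error: missing field '", field,
             "' in section 'input'", call. = FALSE)
      }
      if (!file.exists(config$input[[field]])) {
        stop("input file does not exist: ", config$input[[field]],
             call. = FALSE)
      }
    }
  }
  config
}

#' Run the SIP analysis pipeline end to end
#'
#' Executes, as configured: fraction designation (when fraction metadata is
#' supplied), data acquisition (simulation or TSV input), replicate-averaged
#' profile building, labelling calls, control exclusion, and report writing.
#' Outputs (calls TSV, annotated fraction table, machine-readable JSON
#' summary with status counts, parameters, seed and package version) are
#' written to `output_dir`; no timestamps are embedded, so identical
#' configurations yield byte-identical outputs.
#'
#' @param config Path to a YAML run configuration or an equivalent list;
#'   see [read_run_config()].
#' @param output_dir Overrides `config$output_dir` when given.
#' @return Invisibly, a list with `calls`, `summary` and written `paths`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config <- read_run_config(config)
  out_dir <- output_dir %||% config$output_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  if (!is.null(config$fractions)) {
    meta <- utils::read.delim(config$fractions$metadata,
                              stringsAsFactors = FALSE)
    calib <- do.call(density_calibration,
                     config$fractions$calibration %||% list())
    thr <- do.call(fraction_thresholds,
                   config$fractions$thresholds %||% list())
    meta <- annotate_fractions(meta, calib, thr)
    paths$fractions <- file.path(out_dir, "fractions.tsv")
    write_tsv(meta, paths$fractions)
  }

  truth <- NULL
  if (!is.null(config$input)) {
    abundance <- read_abundance_table(config$input$abundance)
    samples <- read_sample_sheet(config$input$samples)
    if (!is.null(config$input$truth)) {
      truth <- utils::read.delim(config$input$truth, stringsAsFactors = FALSE)
    }
  } else {
    experiment <- simulate_experiment(do.call(sip_sim_config,
                                              config$simulation))
    abundance <- experiment$abundance
    samples <- experiment$samples
    truth <- experiment$truth
  }

  params <- call_params(floor = config$caller$floor, k = config$caller$k)
  calls <- call_experiment(abundance, samples, params,
                           control_treatment = config$caller$control_treatment)
  paths$calls <- file.path(out_dir, "label_calls.tsv")
  write_tsv(calls, paths$calls)

  status_counts <- lapply(split(calls, list(calls$treatment, calls$timepoint),
                                drop = TRUE), function(g) {
    as.list(table(factor(g$final_status,
                         levels = c("labelled", "not_labelled", "below_floor",
                                    "excluded_control"))))
  })
  summary <- list(
    package_version = as.character(utils::packageVersion("methylosip")),
    parameters = list(k = params$k, floor = params$floor,
                      control_treatment = config$caller$control_treatment),
    seed = config$simulation$seed,
    n_taxa = nrow(abundance),
    n_samples = ncol(abundance),
    status_counts = status_counts)
  if (!is.null(truth)) {
    test_trts <- setdiff(unique(calls$treatment),
                         config$caller$control_treatment)
    scored <- calls[calls$treatment %in% test_trts, , drop = FALSE]
    perf <- evaluate_calls(scored, truth)
    summary$sensitivity <- perf$sensitivity
    summary$specificity <- perf$specificity
  }
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(calls = calls, summary = summary, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
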