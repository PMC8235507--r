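#' Pipeline configuration
#'
#' Paths and parameter sets for the end-to-end run: QC, iterative
#' segmentation, configuration classification, and population summary.
#'
#' @param reads Path to the input FASTQ.
#' @param meta Optional sidecar TSV with `read_id n_passes
#'   predicted_accuracy`.
#' @param reference,features Paths to the reference FASTA and feature TSV.
#' @param out_dir Output directory (created if missing).
#' @param qc A [qc_params()].
#' @param align An [align_params()].
#' @param classify A [classify_params()].
#' @param n_bins Bins for the breakpoint-uniformity statistic.
#' @param run_totals Optional named per-run read counts for merged-run
#'   accounting.
#' @param seed Global seed, recorded in every output header.
#' @param verbose Log progress messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, reference, features, out_dir,
                            meta = NULL, qc = qc_params(),
                            align = align_params(),
                            classify = classify_params(), n_bins = 20,
                            run_totals = NULL, seed = 1, verbose = TRUE) {
  structure(list(reads = reads, meta = meta, reference = reference,
                 features = features, out_dir = out_dir, qc = qc,
                 align = align, classify = classify, n_bins = n_bins,
                 run_totals = run_totals, seed = seed, verbose = verbose),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `qc`,
#' `align` and `classify` keys hold parameter maps passed to the respective
#' constructors.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("qc", "align", "classify"))]
  args$qc <- do.call(qc_params, as.list(y$qc))
  args$align <- do.call(align_params, as.list(y$align))
  args$classify <- do.call(classify_params, as.list(y$classify))
  do.call(pipeline_config, args)
}

#' Run the full configuration-analysis pipeline
#'
#' QC-filters the reads, segments each one against the reference by
#' iterative flank realignment, classifies every segment chain, and
#' summarizes the population. Artifacts written to `out_dir`:
#' `filtered.fastq` (+ `filtered.meta.tsv`), `chains.tsv`, `calls.tsv`,
#' `summary.json`, and `pipeline.log`. Outputs carry `#` provenance headers
#' (tool version, seed, config hash) and are identical for identical inputs
#' and configuration. Partial outputs are removed on failure.
#'
#' @param config A [pipeline_config()] or a YAML path.
#' @return Invisibly, a list with the output `paths`, the `summary`, and the
#'   `calls` tibble.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$reads, config$meta, config$reference, config$features)) {
    if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    filtered = file.path(config$out_dir, "filtered"),
    chains = file.path(config$out_dir, "chains.tsv"),
    calls = file.path(config$out_dir, "calls.tsv"),
    summary = file.path(config$out_dir, "summary.json"),
    log = file.path(config$out_dir, "pipeline.log")
  )
  cfg_hash <- rlang::hash(config[setdiff(names(config), "verbose")])
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = paths$log, append = TRUE)
    if (isTRUE(config$verbose)) message(msg)
  }
  cleanup <- function() {
    out <- c(paste0(paths$filtered, c(".fastq", ".meta.tsv")),
             paths$chains, paths$calls, paths$summary)
    unlink(out[file.exists(out)])
  }
  tryCatch({
    unlink(paths$log)
    set.seed(config$seed)
    logline("snapback v", as.character(utils::packageVersion("snapback")),
            " seed=", config$seed, " config=", cfg_hash)
    ref <- read_reference(config$reference, config$features)
    reads <- read_reads(config$reads, config$meta)
    logline("loaded ", nrow(reads), " reads; reference ", ref$length, " nt")
    kept <- qc_filter(reads, config$qc, quiet = !isTRUE(config$verbose))
    qc_counts <- attr(kept, "qc_counts")
    logline("qc: kept ", qc_counts["kept"], "/", qc_counts["input"])
    write_reads(kept, paths$filtered, seed = config$seed)
    chains <- segment_reads(kept, ref, config$align)
    write_chains(chains, paths$chains, seed = config$seed)
    logline("segmented: ", nrow(chains), " segments over ", nrow(kept),
            " reads")
    calls <- classify_chains(chains, kept, ref, config$classify)
    write_calls(calls, paths$calls, seed = config$seed)
    summary <- summarize_population(calls, run_totals = config$run_totals,
                                    ref = ref, n_bins = config$n_bins)
    write_summary_json(summary, paths$summary, seed = config$seed)
    logline("classified ", nrow(calls), " reads: ",
            paste(sprintf("%s=%d", summary$categories$category,
                          summary$categories$n), collapse = " "))
    invisible(list(paths = paths, summary = summary, calls = calls))
  }, error = function(e) {
    cleanup()
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Build the small canonical fixture population
#'
#' Writes an error-free population containing one read per
#' (category, subtype, strand) combination plus ten extra canonical reads,
#' with its truth table, to `dir`. Deterministic for a fixed seed, so
#' regeneration is idempotent.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return The fixture reads tibble, invisibly.
#' @export
make_fixtures <- function(dir = "fixtures", seed = 42) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- build_reference(ref_config(seed = seed))
  withr::with_seed(seed + 1, {
    rows <- list()
    for (st in c("+", "-")) {
      rows <- c(rows, list(
        simulate_canonical(ref, strand = st),
        simulate_snapback(ref, 5, 800, 800, strand = st),
        simulate_snapback(ref, 5, 1000, 600, strand = st),
        simulate_snapback(ref, 3, 900, 900, strand = st),
        simulate_snapback(ref, 3, 1200, 700, strand = st),
        simulate_icg(ref, breakpoint = 2000, strand = st),
        simulate_gdm(ref, 1000, 3500, strand = st)
      ))
    }
    rows <- c(rows, list(simulate_other(1500)),
              lapply(1:10, function(i) simulate_canonical(ref)))
    reads <- dplyr::bind_rows(rows)
    reads$id <- sprintf("fixture_%03d", seq_len(nrow(reads)))
    reads$n_passes <- 10L
    reads$predicted_accuracy <- 0.999
  })
  write_reference(ref, file.path(dir, "reference.fasta"),
                  file.path(dir, "features.tsv"))
  write_reads(reads, file.path(dir, "fixture"), seed = seed)
  invisible(reads)
}
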