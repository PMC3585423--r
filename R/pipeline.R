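#' Pipeline configuration
#'
#' Validated, file-serializable configuration for the simulate -> preprocess
#' -> quantify -> saturate/correlate -> differential-expression pipeline.
#' All stage seeds derive from the single global seed.
#'
#' @param n_reads Reads per simulated library.
#' @param profile `"muscle"` or `"plasma"` composition preset.
#' @param n_mirnas Reference size.
#' @param abundance_shape Log-normal sigma of the abundance profile.
#' @param seed Global integer seed.
#' @param adapter 3' adapter sequence.
#' @param min_len Post-clip minimum length.
#' @param min_overlap Adapter seed length.
#' @param max_snv Quantifier substitution budget.
#' @param three_prime_window Mature 3' tolerance (nt).
#' @param policy Multimapper policy.
#' @param thresholds Detection thresholds for the saturation curve.
#' @param saturation_start,saturation_step Saturation depths (reads).
#' @param correlation_step Correlation-curve depth increment (reads).
#' @param normalization `"tmm"` or `"median_ratio"`.
#' @param alpha FDR level.
#' @param n_per_group Replicates per group for the experiment stage (0
#'   disables differential expression).
#' @param log2fc Named injected log2 fold changes.
#' @param run_saturation,run_correlation Logical stage switches.
#' @return List of class `mirsat_config`.
#' @export
pipeline_config <- function(n_reads = 100000L, profile = c("muscle", "plasma"),
                            n_mirnas = 300L, abundance_shape = 3, seed = 1L,
                            adapter = ILLUMINA_3P_ADAPTER, min_len = 18L,
                            min_overlap = 8L, max_snv = 1L,
                            three_prime_window = 2L, policy = "uniform",
                            thresholds = c(1, 3, 5, 10, 50),
                            saturation_start = 20000L, saturation_step = 20000L,
                            correlation_step = 5000L,
                            normalization = "tmm", alpha = 0.05,
                            n_per_group = 0L, log2fc = numeric(0),
                            run_saturation = TRUE, run_correlation = TRUE) {
  profile <- match.arg(profile)
  cfg <- list(
    n_reads = as.integer(n_reads), profile = profile,
    n_mirnas = as.integer(n_mirnas), abundance_shape = abundance_shape,
    seed = as.integer(seed), adapter = adapter, min_len = as.integer(min_len),
    min_overlap = as.integer(min_overlap), max_snv = as.integer(max_snv),
    three_prime_window = as.integer(three_prime_window), policy = policy,
    thresholds = as.numeric(thresholds),
    saturation_start = as.integer(saturation_start),
    saturation_step = as.integer(saturation_step),
    correlation_step = as.integer(correlation_step),
    normalization = normalization, alpha = alpha,
    n_per_group = as.integer(n_per_group), log2fc = log2fc,
    run_saturation = isTRUE(run_saturation),
    run_correlation = isTRUE(run_correlation)
  )
  stopifnot(
    cfg$n_reads >= 0, cfg$n_mirnas >= 1, cfg$min_len >= 1,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$policy %in% c("uniform", "em", "discard"),
    cfg$normalization %in% c("tmm", "median_ratio")
  )
  structure(cfg, class = "mirsat_config")
}

#' Serialize / restore a pipeline configuration
#'
#' JSON round trip is lossless for every field.
#'
#' @param config `pipeline_config()` object.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$log2fc <- as.list(x$log2fc) # keep miRNA names through JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fc <- unlist(x$log2fc) %||% numeric(0)
  do.call(pipeline_config, c(
    x[setdiff(names(x), c("log2fc", "run_saturation", "run_correlation"))],
    list(log2fc = fc, run_saturation = x$run_saturation,
         run_correlation = x$run_correlation)
  ))
}

#' Run the full pipeline on one simulated sample
#'
#' Simulates a library from the configured composition preset, preprocesses
#' and quantifies it, optionally runs the saturation and correlation curves
#' on it, and (when `n_per_group >= 2`) simulates and tests a two-group
#' experiment. Reruns with the same config are identical. The report carries
#' the accounting triplet (initial, post-clipped, mapped reads), which must
#' be non-increasing.
#'
#' @param config `pipeline_config()` object.
#' @return List of class `mirsat_report`; see Details.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mirsat_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mirsat(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
                  "mirsat_pipeline_failure")
    })
  }
  ref <- stage("reference", build_reference(config$n_mirnas, seed = derive_seed(config$seed, 1L),
                                            adapter = config$adapter))
  decoys <- stage("reference", decoy_pools(ref, seed = derive_seed(config$seed, 2L),
                                           adapter = config$adapter))
  profile <- stage("reference", simulate_abundances(ref, shape = config$abundance_shape,
                                                    seed = derive_seed(config$seed, 3L)))
  comp <- if (config$profile == "muscle") composition_muscle() else composition_plasma()
  cfg <- sim_config(config$n_reads, seed = derive_seed(config$seed, 4L),
                    adapter = config$adapter)
  lib <- stage("simulate", simulate_library(ref, profile, comp, cfg, decoys))
  qc <- stage("preprocess", qc_summary(lib$reads))
  pre <- stage("preprocess", preprocess_reads(lib$reads, config$adapter,
                                              config$min_len, config$min_overlap))
  quant <- stage("quantify", quantify_sample(pre$collapsed, ref, decoys,
                                             config$max_snv, config$three_prime_window,
                                             config$policy))
  report <- list(
    seed = config$seed,
    config = config,
    tool_version = as.character(utils::packageVersion("mirsat")),
    qc_pass = qc$pass,
    n_initial = nrow(lib$reads),
    n_postclipped = pre$report$n_retained,
    n_mapped = quant$library_size,
    clip_report = pre$report,
    composition = quant$composition
  )
  if (report$n_initial < report$n_postclipped || report$n_postclipped < report$n_mapped) {
    stop_mirsat("read accounting violated: initial >= post-clipped >= mapped",
                "mirsat_pipeline_failure")
  }
  if (config$run_saturation && sum(pre$collapsed$count) >= config$saturation_start) {
    qf <- make_quantifier(ref, decoys, config$max_snv, config$three_prime_window,
                          config$policy)
    report$saturation <- stage("saturate", detection_curve(
      pre$collapsed, qf, start = config$saturation_start,
      step = config$saturation_step, thresholds = config$thresholds,
      seed = derive_seed(config$seed, 5L)
    ))$curve
  }
  if (config$run_correlation && quant$library_size >= config$correlation_step) {
    mapped <- round(quant$counts)
    report$correlation <- stage("correlate", correlation_curve(
      mapped, step = config$correlation_step, seed = derive_seed(config$seed, 6L)
    ))$curve
  }
  if (config$n_per_group >= 2L) {
    truth <- experiment_truth(ref, config$log2fc, n_per_group = config$n_per_group)
    exp <- stage("simulate", simulate_experiment(ref, profile, comp, truth, cfg, decoys))
    quants <- stage("quantify", lapply(exp$libraries, function(l) {
      quantify_sample(preprocess_reads(l$reads, config$adapter, config$min_len,
                                       config$min_overlap)$collapsed,
                      ref, decoys, config$max_snv, config$three_prime_window,
                      config$policy)
    }))
    ct <- count_table(quants)
    report$de <- stage("diffexp", de_exact_test(
      suppressMessages(round_counts(ct$counts)), exp$groups,
      normalization = config$normalization, alpha = config$alpha
    ))$table
    report$truth <- truth$table
  }
  structure(report, class = "mirsat_report")
}
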