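# End-to-end orchestration: simulate or load a cohort, run both decision
# engines, build the paired tables and statistics, and write a
# deterministic report bundle (CSV decisions, TSV report, text report,
# JSON manifest).

#' Pipeline configuration
#'
#' Exactly one of `simulate` / `input_cohort` must be given.
#'
#' @param simulate a [cohort_params()], or `NULL` to read a cohort.
#' @param input_cohort path of a cohort CSV (see [read_cohort()]), or `NULL`.
#' @param nsc an [nsc_config()].
#' @param sco an [sco_config()].
#' @param comparison list of comparison options: `mcnemar` variant, `ci`
#'   method, `rounding` (decimal places in the text report).
#' @param output_dir directory for the report bundle.
#' @param seed integer seed applied before any random draw.
#' @param log_level `"quiet"`, `"info"`, or `"debug"` (messages to stderr).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL,
                            input_cohort = NULL,
                            nsc = nsc_config(),
                            sco = sco_config(),
                            comparison = list(mcnemar = "exact_binomial",
                                              ci = "wald_paired",
                                              rounding = 2),
                            output_dir = tempfile("eoscompare_run_"),
                            seed = 1L,
                            log_level = c("info", "quiet", "debug")) {
  log_level <- match.arg(log_level)
  if (is.null(simulate) == is.null(input_cohort))
    stop("schema error: exactly one of simulate / input_cohort must be set")
  structure(list(simulate = simulate, input_cohort = input_cohort,
                 nsc = nsc, sco = sco, comparison = comparison,
                 output_dir = output_dir, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `simulate:`, `nsc:`, `sco:`, `comparison:`,
#' `input_cohort`, `output_dir`, `seed`, `log_level`; each engine key holds
#' arguments of the corresponding constructor.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  # keep the single-letter key `n` (cohort size) from being parsed as a
  # YAML 1.1 boolean, while still honouring true/false values
  y <- yaml::read_yaml(path, handlers = list(
    "bool#no" = function(x) if (identical(x, "n")) "n" else FALSE,
    "bool#yes" = function(x) if (identical(x, "y")) "y" else TRUE))
  args <- list(
    simulate = if (!is.null(y$simulate)) do.call(cohort_params, y$simulate),
    input_cohort = y$input_cohort,
    nsc = if (!is.null(y$nsc)) do.call(nsc_config, y$nsc) else nsc_config(),
    sco = if (!is.null(y$sco)) do.call(sco_config, y$sco) else sco_config()
  )
  if (!is.null(y$comparison)) args$comparison <-
    utils::modifyList(list(mcnemar = "exact_binomial", ci = "wald_paired",
                           rounding = 2), y$comparison)
  if (!is.null(y$output_dir)) args$output_dir <- y$output_dir
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$log_level)) args$log_level <- y$log_level
  do.call(pipeline_config, args)
}

pipeline_log <- function(config, level, ...) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  if (levels[[config$log_level]] >= levels[[level]])
    message("[eoscompare] ", ...)
}

format_num <- function(x, digits) formatC(x, format = "f", digits = digits)

comparison_block <- function(tab, label, config) {
  mc <- mcnemar_test(tab, config$comparison$mcnemar)
  pd <- paired_difference(tab, config$comparison$ci)
  mr <- marginal_rates(tab)
  data.frame(
    comparison = label,
    a = tab$a, b = tab$b, c = tab$c, d = tab$d, n = tab$n,
    sco_pct = mr$sco_pct, nsc_pct = mr$nsc_pct,
    diff_pct = pd$diff_pct,
    diff_rounded_marginals_pct = rounded_marginal_difference(tab),
    ci_low_pct = pd$ci_low_pct, ci_high_pct = pd$ci_high_pct,
    ci_method = pd$method,
    mcnemar_variant = mc$variant, mcnemar_p = mc$p_value,
    stringsAsFactors = FALSE
  )
}

#' Run the full comparison pipeline
#'
#' Simulates (or loads) a cohort, runs both decision engines, builds
#' paired antibiotic and evaluation tables for the whole cohort and the
#' late-preterm stratum, computes McNemar tests and paired differences,
#' and writes a deterministic report bundle: cohort CSVs (if simulated),
#' per-strategy decision CSVs, `paired_comparisons.tsv`,
#' `rates_by_stratum.tsv`, `report.txt`, and `manifest.json` (seed, config
#' echo, package version). Identical configuration and seed reproduce the
#' bundle byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the cohort, both decision frames, the
#'   paired tables, the comparison data frame, and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  if (!is.null(config$simulate)) {
    params <- config$simulate
    if (is.null(params$seed)) params$seed <- config$seed
    pipeline_log(config, "info", "simulating cohort of n = ", params$n)
    cohort <- generate_cohort(params)
    write_cohort(cohort, file.path(config$output_dir, "cohort.csv"))
  } else {
    pipeline_log(config, "info", "reading cohort from ", config$input_cohort)
    cohort <- read_cohort(config$input_cohort)
  }
  pipeline_log(config, "info", "running decision engines")
  sco <- run_sco_cohort(cohort, config$sco)
  nsc <- run_nsc(cohort, config$nsc)
  utils::write.csv(sco, file.path(config$output_dir, "decisions_sco.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(nsc, file.path(config$output_dir, "decisions_nsc.csv"),
                   row.names = FALSE, na = "")
  rec <- cohort$records
  lp_ids <- rec$id[rec$gestational_age_weeks < 37]
  tables <- list(
    antibiotics_all = build_paired_table(sco, nsc, "antibiotics"),
    evaluated_all = build_paired_table(sco, nsc, "evaluated"),
    antibiotics_late_preterm = build_paired_table(sco, nsc, "antibiotics",
                                                  ids = lp_ids),
    evaluated_late_preterm = build_paired_table(sco, nsc, "evaluated",
                                                ids = lp_ids)
  )
  comparisons <- do.call(rbind, lapply(names(tables), function(nm)
    comparison_block(tables[[nm]], nm, config)))
  rates <- summarize_rates(cohort, sco, nsc)
  utils::write.table(comparisons,
                     file.path(config$output_dir, "paired_comparisons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(rates,
                     file.path(config$output_dir, "rates_by_stratum.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  dg <- config$comparison$rounding %||% 2
  txt <- c(
    "Comparison of EOS management strategies (SCO vs NSC)",
    sprintf("cohort: n = %d neonates", nrow(rec)),
    "",
    unlist(lapply(seq_len(nrow(comparisons)), function(i) {
      r <- comparisons[i, ]
      c(sprintf("%s: SCO %s%%, NSC %s%%, difference %s%% (95%% CI %s to %s), McNemar p = %s",
                r$comparison,
                format_num(r$sco_pct, 1), format_num(r$nsc_pct, 1),
                format_num(r$diff_pct, dg),
                format_num(r$ci_low_pct, dg), format_num(r$ci_high_pct, dg),
                format(r$mcnemar_p, digits = 3)),
        sprintf("  cells (a,b,c,d) = (%d, %d, %d, %d)", r$a, r$b, r$c, r$d))
    }))
  )
  writeLines(txt, file.path(config$output_dir, "report.txt"))
  manifest <- list(
    package = "eoscompare",
    version = as.character(utils::packageVersion("eoscompare")),
    seed = config$seed,
    simulated = !is.null(config$simulate),
    n = nrow(rec),
    nsc = config$nsc[!vapply(config$nsc, is.function, logical(1L))],
    sco = unclass(config$sco),
    comparison = config$comparison,
    simulate = if (!is.null(config$simulate))
      unclass(config$simulate)[setdiff(names(config$simulate),
                                       c("ga_late", "ga_term", "trajectory"))]
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  pipeline_log(config, "info", "report bundle written to ",
               config$output_dir)
  invisible(list(cohort = cohort, sco = sco, nsc = nsc, tables = tables,
                 comparisons = comparisons, rates = rates,
                 output_dir = config$output_dir))
}
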