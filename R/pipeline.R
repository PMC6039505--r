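# One-call orchestration: read the configured inputs, standardize each
# study x sex, rebin and meta-analyse per stratum, form the age-standardized
# meta-estimate with its Monte-Carlo interval, optionally project case
# burden and analyse a cohort, and write every stage's table plus a run log.
# All outputs embed the seed and the md5 of the config file so a run can be
# audited and reproduced byte for byte.

#' Run the full prevalence-estimation pipeline from a config
#'
#' The config (YAML file or an equivalent named list) names the inputs and
#' tuning parameters:
#' \describe{
#'   \item{study_table}{path to the stratified count table (required).}
#'   \item{std_pop}{path to the standard-population table (required).}
#'   \item{projection}{optional path to a projection population table;
#'     stratum meta-rates are applied to it.}
#'   \item{cohort}{optional path to a cohort table, with
#'     \code{cohort_age_lo}/\code{cohort_age_hi} giving the stratum to
#'     analyse and \code{n_boot} bootstrap replicates.}
#'   \item{meta_breaks}{optional cut points for rebinning the study table
#'     before meta-analysis (e.g. \code{c(45, 55, 65, 75, 85, Inf)}).}
#'   \item{method, variance}{tau^2 estimator and within-study variance model
#'     (defaults REML, poisson).}
#'   \item{n_draws, seed, level}{Monte-Carlo draws (default 1e6), seed
#'     (required), confidence level (default 0.95).}
#'   \item{out_dir}{directory for the result tables and log (required).}
#' }
#' All referenced files are checked before any stage runs; a stage failure
#' aborts with the stage name.
#'
#' @param config Path to a YAML config file, or a named list.
#' @return Invisibly, a list of class `"prev_pipeline"` with elements
#'   `standardized` (per study x sex [std_rate()] summaries), `meta`
#'   (the [meta_by_stratum()] table), `meta_standardized` (combined and, when
#'   both sexes are present, per-sex [meta_std_rate()] objects), `projection`
#'   and `cohort` (when configured), `seed`, `config_md5` and `files`.
#' @export
run_pipeline <- function(config) {
  config_md5 <- NA_character_
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config_md5 <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (key in c("study_table", "std_pop", "seed", "out_dir")) {
    if (is.null(config[[key]])) stop("config is missing '", key, "'",
                                     call. = FALSE)
  }
  # pre-run validation: every referenced file must exist
  paths <- unlist(config[c("study_table", "std_pop", "projection", "cohort")])
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("pre-run validation: input file(s) not found: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  seed <- as.integer(config$seed)
  level <- config$level %||% 0.95
  n_draws <- config$n_draws %||% 1e6
  method <- config$method %||% "REML"
  variance <- config$variance %||% "poisson"
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  study <- stage("read", read_study_table(config$study_table))
  std <- stage("read", read_standard_population(config$std_pop))

  # --- standardize: one row per study x sex, Table-1-style ----------------
  std_rows <- list()
  fits <- list()
  for (g in split(study, list(study$study_id, study$sex), drop = TRUE)) {
    key <- paste(g$study_id[1], g$sex[1], sep = ".")
    # standardize within the matching sex of the standard population when it
    # is sex-specific; otherwise use the combined table
    sub_std <- if (any(std$sex == g$sex[1])) {
      std[std$sex == g$sex[1], , drop = FALSE]
    } else {
      std
    }
    sub_std <- standard_population(sub_std$age_lo, sub_std$age_hi,
                                   sub_std$count, sub_std$sex)
    fit <- stage("standardize", std_rate(g, sub_std, level = level))
    fits[[key]] <- fit
    std_rows[[key]] <- data.frame(
      study_id = g$study_id[1], sex = g$sex[1],
      population = sum(g$population), cases = sum(g$cases),
      std_rate = fit$rate, ci_low = fit$ci[1], ci_high = fit$ci[2])
  }
  standardized <- do.call(rbind, std_rows)
  rownames(standardized) <- NULL

  # --- meta-analysis per sex x stratum ------------------------------------
  meta_input <- if (!is.null(config$meta_breaks)) {
    stage("rebin", rebin_counts(study, as.numeric(config$meta_breaks)))
  } else {
    study
  }
  meta <- stage("meta", meta_by_stratum(meta_input, method = method,
                                        variance = variance, level = level))

  # --- age-standardized meta-estimate -------------------------------------
  msr <- list()
  msr$combined <- stage("meta-standardize",
                        meta_std_rate(meta, std, n_draws = n_draws,
                                      seed = seed, level = level))
  sexes <- intersect(c("female", "male"), unique(std$sex))
  for (s in sexes) {
    sub <- std[std$sex == s, , drop = FALSE]
    sub <- standard_population(sub$age_lo, sub$age_hi, sub$count, sub$sex)
    msr[[s]] <- stage("meta-standardize",
                      meta_std_rate(meta[meta$sex == s, , drop = FALSE], sub,
                                    n_draws = n_draws, seed = seed + match(s, sexes),
                                    level = level))
  }

  # --- projection ---------------------------------------------------------
  projection <- NULL
  if (!is.null(config$projection)) {
    proj_pop <- stage("project", read_standard_population(config$projection))
    projection <- stage("project", project_counts(meta, proj_pop))
  }

  # --- cohort person-time -------------------------------------------------
  cohort <- NULL
  if (!is.null(config$cohort)) {
    ct <- stage("cohort", read_cohort_table(config$cohort))
    cohort <- stage("cohort", person_time_prevalence(
      ct, config$cohort_age_lo %||% 45, config$cohort_age_hi %||% Inf,
      n_boot = config$n_boot %||% 10000, seed = seed, level = level))
  }

  # --- outputs ------------------------------------------------------------
  hdr <- c(paste0("# seed: ", seed),
           paste0("# config_md5: ", config_md5),
           paste0("# tau2_method: ", method))
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, open = "wt")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
    path
  }
  files <- c(
    summary = emit(standardized, "summary.csv"),
    meta = emit(as.data.frame(meta), "meta.csv"))
  ms_tab <- do.call(rbind, lapply(names(msr), function(nm) {
    m <- msr[[nm]]
    data.frame(group = nm, rate = m$rate, ci_low = m$ci[1],
               ci_high = m$ci[2], n_draws = m$n_draws, seed = m$seed)
  }))
  files <- c(files, meta_standardized = emit(ms_tab, "meta_standardized.csv"))
  if (!is.null(projection)) {
    files <- c(files, projection = emit(projection$table, "projection.csv"))
  }
  if (!is.null(cohort)) {
    ch_tab <- data.frame(age_lo = cohort$age_lo, age_hi = cohort$age_hi,
                         person_years = cohort$person_years,
                         case_years = cohort$case_years, rate = cohort$rate,
                         ci_low = cohort$ci[1], ci_high = cohort$ci[2],
                         n_boot = cohort$n_boot)
    files <- c(files, cohort = emit(ch_tab, "cohort.csv"))
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    "metaprev pipeline run",
    paste0("seed: ", seed),
    paste0("config_md5: ", config_md5),
    paste0("tau2_method: ", method),
    paste0("variance_model: ", variance),
    paste0("n_draws: ", format(n_draws, scientific = FALSE)),
    paste0("level: ", level),
    paste0("outputs: ", paste(basename(files), collapse = ", "))),
    log_path)
  files <- c(files, log = log_path)

  invisible(structure(list(standardized = standardized, std_fits = fits,
                           meta = meta, meta_standardized = msr,
                           projection = projection, cohort = cohort,
                           seed = seed, config_md5 = config_md5,
                           files = files),
                      class = "prev_pipeline"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.prev_pipeline <- function(x, ...) {
  cat("Prevalence pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("\nStandardized rates per study x sex:\n")
  tab <- x$standardized
  tab$std_rate <- round(tab$std_rate)
  tab$ci_low <- round(tab$ci_low)
  tab$ci_high <- round(tab$ci_high)
  print(tab, row.names = FALSE)
  cat("\nAge-standardized meta-estimates:\n")
  for (nm in names(x$meta_standardized)) {
    m <- x$meta_standardized[[nm]]
    cat(sprintf("  %-9s %.0f per 100,000 (%d%% MC CI %.0f-%.0f)\n", nm,
                m$rate, round(100 * m$level), m$ci[1], m$ci[2]))
  }
  if (!is.null(x$projection)) {
    cat(sprintf("\nProjected cases: %.0f (rounded per-stratum sum %.0f)\n",
                x$projection$total, x$projection$total_rounded))
  }
  invisible(x)
}
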