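#' Configure an end-to-end reproducibility run
#'
#' Two entry modes: `"table"` draws readings directly from the log-normal
#' cohort model (the statistics core without the imaging layer), `"phantom"`
#' runs the full voxel pipeline. The configuration round-trips losslessly
#' through JSON or YAML ([write_run_config()], [read_run_config()]), and the
#' seed is recorded in every output.
#'
#' @param mode "table" or "phantom".
#' @param n_treatments,n_observers Cohort design; defaults 25 and 3.
#' @param quantities Quantities to analyze; default all four.
#' @param rules List of [threshold_rule()]s; default [builtin_rules()].
#' @param n_bootstrap Bootstrap replicates for RDC CIs; default 2000.
#' @param alpha Level for the normality gate and tests; default 0.05.
#' @param seed Master seed; default 1.
#' @param output_dir Optional directory where [run_pipeline()] writes the
#'   cohort CSV, the JSON report and the resolved config.
#' @param cohort Named list of overrides for [default_cohort_model()]
#'   (table mode).
#' @param phantom Named list of overrides for [simulate_phantom_cohort()]
#'   (phantom mode).
#' @return A `run_config`.
#' @export
run_config <- function(mode = c("table", "phantom"), n_treatments = 25L,
                       n_observers = 3L,
                       quantities = c("TV", "TLV", "TD", "THLD"),
                       rules = builtin_rules(), n_bootstrap = 2000L,
                       alpha = 0.05, seed = 1L, output_dir = NULL,
                       cohort = list(), phantom = list()) {
  mode <- match.arg(mode)
  quantities <- match.arg(quantities, names(.quantity_cols), several.ok = TRUE)
  if (n_treatments < 2L || n_observers < 2L)
    stop("invalid config: need >= 2 treatments and >= 2 observers")
  rules <- lapply(rules, function(r) {
    if (inherits(r, "threshold_rule")) r
    else threshold_rule(r$quantity, r$cutoff, r$direction,
                        if (is.null(r$label)) NULL else r$label)
  })
  if (!is.finite(seed) || abs(seed) >= 2^31) stop("seed must be a 32-bit integer")
  structure(list(mode = mode, n_treatments = as.integer(n_treatments),
                 n_observers = as.integer(n_observers),
                 quantities = quantities, rules = rules,
                 n_bootstrap = as.integer(n_bootstrap), alpha = alpha,
                 seed = as.integer(seed), output_dir = output_dir,
                 cohort = cohort, phantom = phantom),
            class = "run_config")
}

#' Read / write a run configuration (JSON or YAML)
#'
#' Format is chosen by file extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_run_config` returns a validated `run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- unclass(config)
  lst$rules <- lapply(lst$rules, unclass)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(lst, path)
  else
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  do.call(run_config, lst[!vapply(lst, is.null, logical(1))])
}

#' Full agreement analysis of an observer table
#'
#' Computes, for each requested quantity: per-observer summary statistics,
#' the three-way and all pairwise ICCs ([icc_agreement()]), pairwise CVs,
#' pairwise Bland-Altman analyses, the RDC with bootstrap CI ([rdc()]), and
#' the normality-gated location tests ([compare_readers()]); plus, for each
#' threshold rule, the cross-observer classification concordance. Every
#' numeric block in the report carries its unit.
#'
#' @param table An `observer_dose_table`.
#' @param quantities Quantities to analyze.
#' @param rules List of [threshold_rule()]s.
#' @param n_bootstrap,seed,alpha,conf Analysis settings; RDC bootstrap seeds
#'   are derived deterministically from `seed`.
#' @return An `agreement_report` (plain nested list, JSON-ready).
#' @export
analyze_cohort <- function(table, quantities = c("TV", "TLV", "TD", "THLD"),
                           rules = builtin_rules(), n_bootstrap = 2000L,
                           seed = 1L, alpha = 0.05, conf = 0.95) {
  table <- observer_table(as.data.frame(table))
  obs <- sort(unique(table$observer_id))
  k <- length(obs)
  pairs <- utils::combn(k, 2)

  qrep <- list()
  for (qi in seq_along(quantities)) {
    q <- quantities[qi]
    m <- readings_matrix(table, q)
    summ <- lapply(seq_len(k), function(j)
      list(observer = obs[j], mean = mean(m[, j]), sd = sd(m[, j]),
           median = median(m[, j]), min = min(m[, j]), max = max(m[, j])))
    icc_all <- .icc_as_list(icc_agreement(m, conf))
    icc_pair <- list(); cv_pair <- list(); ba_pair <- list()
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; b <- pairs[2, p]
      key <- paste(obs[a], "vs", obs[b])
      icc_pair[[key]] <- .icc_as_list(icc_agreement(m[, c(a, b)], conf))
      cv_pair[[key]] <- pairwise_cv(m[, a], m[, b])
      ba_pair[[key]] <- .ba_as_list(bland_altman(m[, a], m[, b]))
    }
    rd <- rdc(m, n_bootstrap = n_bootstrap, seed = seed + 1000L + qi)
    qrep[[q]] <- list(
      unit = unname(.quantity_units[[q]]),
      summary = summ,
      icc = c(list(`all observers` = icc_all), icc_pair),
      cv_percent = cv_pair,
      bland_altman = ba_pair,
      rdc = .rdc_as_list(rd),
      comparison = .cmp_as_list(compare_readers(m, alpha))
    )
  }

  conc <- lapply(rules, function(r) {
    cr <- discordance_fraction(table, r)
    list(rule = r$label, unit = "Gy",
         n_treatments = cr$n_treatments, n_discordant = cr$n_discordant,
         fraction_discordant = cr$fraction_discordant)
  })

  structure(list(n_treatments = attr(table, "n_treatments"),
                 n_observers = k, observers = obs,
                 quantities = qrep, concordance = conc),
            class = "agreement_report")
}

.icc_as_list <- function(x)
  list(estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
       model = x$model_label, low_n = x$low_n)

.ba_as_list <- function(x)
  list(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
       loa_high = x$loa_high, n = x$n,
       points = list(mean = x$points$mean, difference = x$points$difference))

.rdc_as_list <- function(x)
  list(estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
       sigma_within_log = x$sigma_within_log, q95_range_k = x$q95_range_k,
       n_bootstrap = x$n_bootstrap)

.cmp_as_list <- function(x)
  list(family = x$family, normality_p = as.list(x$normality_p),
       overall = x$overall,
       pairwise = lapply(seq_len(nrow(x$pairwise)), function(i)
         as.list(x$pairwise[i, ])))

#' Run the pipeline end-to-end
#'
#' simulate (table or phantom mode) -> analyze -> classify -> report.
#' Deterministic given the config seed. When `config$output_dir` is set,
#' writes `cohort.csv`, `report.json` and `config.json` there; on a stage
#' failure, outputs already written are retained and the error names the
#' stage.
#'
#' @param config A `run_config`.
#' @return The `agreement_report`, with a `provenance` block (seed, config
#'   MD5 hash, package version, timestamp).
#' @export
#' @examples
#' cfg <- run_config("table", n_treatments = 10, n_bootstrap = 50, seed = 7)
#' rep <- run_pipeline(cfg)
#' rep$quantities$TD$rdc$estimate
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  table <- .run_stage("simulate", {
    if (config$mode == "table") {
      model <- do.call(default_cohort_model,
                       c(list(n_treatments = config$n_treatments,
                              n_observers = config$n_observers),
                         config$cohort))
      simulate_cohort(model, seed = config$seed)
    } else {
      do.call(simulate_phantom_cohort,
              c(list(n_treatments = config$n_treatments,
                     n_observers = config$n_observers, seed = config$seed),
                config$phantom))
    }
  })
  if (!is.null(out_dir))
    write_observer_table(table, file.path(out_dir, "cohort.csv"))

  report <- .run_stage("analyze", {
    analyze_cohort(table, quantities = config$quantities,
                   rules = config$rules, n_bootstrap = config$n_bootstrap,
                   seed = config$seed, alpha = config$alpha)
  })
  report$provenance <- list(
    seed = config$seed,
    mode = config$mode,
    config_md5 = .config_hash(config),
    package_version = as.character(packageVersion("sirtagree")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(out_dir)) {
    write_run_config(config, file.path(out_dir, "config.json"))
    write_agreement_report(report, file.path(out_dir, "report.json"))
  }
  report
}

.run_stage <- function(stage, expr) {
  tryCatch(force(expr), error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_run_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Read / write an agreement report as JSON
#'
#' Reports are written with unboxed scalars and full numeric precision, so
#' an identical analysis yields byte-identical JSON (the timestamp in the
#' provenance block being the only run-dependent field). `read -> write`
#' round-trips to identical bytes.
#'
#' @param report An `agreement_report`.
#' @param path File path.
#' @return `read_agreement_report` returns the report structure;
#'   `write_agreement_report` returns `path` invisibly.
#' @export
write_agreement_report <- function(report, path) {
  jsonlite::write_json(.strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       null = "null")
  invisible(path)
}

#' @rdname write_agreement_report
#' @export
read_agreement_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

.strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, .strip_classes)
  } else x
}
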