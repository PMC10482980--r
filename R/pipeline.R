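# End-to-end analysis: trial logs (any CSV dialect via a column/value
# mapping) -> per-group frequency tables -> base fit -> battery of nested
# equality tests -> report with journal-style formatting and full-precision
# JSON.

#' Column and value mapping for a trial-log dialect
#'
#' Deposited logs rarely share a schema, so ingestion is driven entirely by
#' a user-editable mapping from the file's columns and value codes to the
#' canonical ones. The default describes the canonical dialect written by
#' [write_trial_log()].
#'
#' @param columns Named character vector mapping canonical names
#'   (`participant_id`, `group`, `trial`, `phase`, `partner`,
#'   `participant`, `punish_invest`) to the file's column names.
#' @param cooperate,defect Value codes for the two decisions.
#' @param training,test Value codes for the two phases.
#' @return Object of class `"cp_log_mapping"`.
#' @export
#' @examples
#' # a dialect with different headers and long decision codes:
#' log_mapping(columns = c(participant_id = "subj", group = "cond",
#'                         trial = "t", phase = "block",
#'                         partner = "other", participant = "own",
#'                         punish_invest = "pun"),
#'             cooperate = "coop", defect = "defect")
log_mapping <- function(columns = c(participant_id = "participant_id",
                                    group = "group", trial = "trial",
                                    phase = "phase", partner = "partner",
                                    participant = "participant",
                                    punish_invest = "punish_invest"),
                        cooperate = "C", defect = "D",
                        training = "training", test = "test") {
  needed <- .trial_log_cols
  if (!all(needed %in% names(columns)))
    stop("`columns` must map all of: ", paste(needed, collapse = ", "),
         call. = FALSE)
  structure(list(columns = columns[needed],
                 codes = list(cooperate = cooperate, defect = defect,
                              training = training, test = test)),
            class = "cp_log_mapping")
}

.decode <- function(values, mapping, what, codes_wanted) {
  lut <- stats::setNames(codes_wanted,
                         unlist(mapping$codes[codes_wanted]))
  # values already in canonical form pass through (internal data.frames)
  decoded <- ifelse(values %in% codes_wanted, values,
                    lut[as.character(values)])
  bad <- which(is.na(decoded))
  if (length(bad))
    stop(sprintf("unknown %s code(s) %s at row(s) %s", what,
                 paste(unique(values[bad]), collapse = ", "),
                 paste(utils::head(bad, 10), collapse = ", ")),
         call. = FALSE)
  decoded
}

#' Aggregate a trial log into per-group frequency tables
#'
#' Training trials are excluded; every test trial is mapped to one of the
#' eight response categories (punishment binarized at invest > 0) and
#' counted per group.
#'
#' @param log Trial-log data.frame, or a CSV path.
#' @param mapping A [log_mapping()] describing the log's dialect.
#' @return Named list of [cp_freq_table()], one per group, in order of
#'   first appearance.
#' @export
#' @examples
#' d <- group_design("g1", cp_theta(0.6, 0.4, 0.2, 0.1, 0.1), 20)
#' tabs <- aggregate_trials(simulate_trials(d, seed = 1))
#' tabs$g1
aggregate_trials <- function(log, mapping = log_mapping()) {
  stopifnot(inherits(mapping, "cp_log_mapping"))
  if (is.character(log)) log <- utils::read.csv(log, stringsAsFactors = FALSE)
  cols <- mapping$columns
  missing_cols <- setdiff(unname(cols), names(log))
  if (length(missing_cols))
    stop("trial log is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- data.frame(
    participant_id = log[[cols[["participant_id"]]]],
    group = log[[cols[["group"]]]],
    trial = log[[cols[["trial"]]]],
    phase = .decode(log[[cols[["phase"]]]], mapping, "phase",
                    c("training", "test")),
    partner = .decode(log[[cols[["partner"]]]], mapping, "partner decision",
                      c("cooperate", "defect")),
    participant = .decode(log[[cols[["participant"]]]], mapping,
                          "participant decision", c("cooperate", "defect")),
    punish_invest = log[[cols[["punish_invest"]]]],
    stringsAsFactors = FALSE)
  if (!is.numeric(x$punish_invest) || any(is.na(x$punish_invest)) ||
      any(x$punish_invest < 0))
    stop("punishment investments must be non-negative numbers",
         call. = FALSE)
  key <- paste(x$participant_id, x$trial, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (participant, trial) key(s) at row(s) ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  x <- x[x$phase == "test", ]
  if (nrow(x) == 0L)
    stop("no test-phase trials in the log (only training trials found)",
         call. = FALSE)
  groups <- unique(x$group)
  cc <- cp_categories()
  out <- list()
  for (g in groups) {
    xg <- x[x$group == g, ]
    cat_idx <- match(paste(xg$partner, xg$participant,
                           ifelse(xg$punish_invest > 0,
                                  "punished", "not_punished"), sep = ":"),
                     cp_category_labels())
    counts <- tabulate(cat_idx, nbins = 8L)
    out[[g]] <- cp_freq_table(counts)
  }
  out
}

#' Default test battery: every parameter, every pair of groups
#'
#' @param groups Character vector of group labels.
#' @param parameters Parameters to compare; default all five.
#' @return List of `list(parameter =, groups =)` battery entries, one per
#'   parameter x group pair.
#' @export
default_battery <- function(groups, parameters = .cp_par_names) {
  stopifnot(length(groups) >= 2L)
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  out <- list()
  for (p in parameters) for (pr in pairs)
    out[[length(out) + 1L]] <- list(parameter = p, groups = pr)
  out
}

#' Configuration of a full analysis run
#'
#' @param input Trial-log data.frame or CSV path.
#' @param mapping A [log_mapping()] for the input's dialect.
#' @param groups Group labels in fixed order; `NULL` takes them from the
#'   data in order of first appearance.
#' @param battery List of `list(parameter =, groups =)` comparisons; `NULL`
#'   builds [default_battery()] over all groups.
#' @param alpha Significance level annotated in the report.
#' @param seed Seed for the fit restarts.
#' @param bonferroni If `TRUE`, the report annotates each comparison with a
#'   Bonferroni-adjusted p value (primary output unchanged: the tests are
#'   reported unadjusted).
#' @return Object of class `"cp_analysis_config"`.
#' @export
cp_analysis_config <- function(input, mapping = log_mapping(),
                               groups = NULL, battery = NULL,
                               alpha = 0.05, seed = 42L,
                               bonferroni = FALSE) {
  structure(list(input = input, mapping = mapping, groups = groups,
                 battery = battery, alpha = alpha, seed = as.integer(seed),
                 bonferroni = isTRUE(bonferroni)),
            class = "cp_analysis_config")
}

#' Run the full analysis: base fit plus the battery of equality tests
#'
#' Aggregates the input log, fits the unconstrained base model (one model
#' instance per group), then runs one nested equality test per battery
#' entry. Human-readable output rounds as is conventional (G^2 and delta
#' G^2 to 2 decimals, p to 3, w to 2, with "< 0.01" / "< 0.001" for
#' positive values that would display as zero); the returned object and
#' its JSON serialization keep full precision.
#'
#' @param config A [cp_analysis_config()].
#' @return Object of class `"cp_report"`: `fit` (base [fit_cp()] result),
#'   `tests` (list of [cp_nested_test()] results, one per battery entry,
#'   in order), `tables`, `battery`, `alpha`, and a `provenance` block
#'   (config hash, seed, package version).
#' @export
run_cp_analysis <- function(config) {
  stopifnot(inherits(config, "cp_analysis_config"))
  t0 <- proc.time()[["elapsed"]]
  tables <- aggregate_trials(config$input, config$mapping)
  groups <- config$groups
  if (is.null(groups)) groups <- names(tables)
  if (!all(groups %in% names(tables)))
    stop("configured group(s) not present in the data: ",
         paste(setdiff(groups, names(tables)), collapse = ", "),
         call. = FALSE)
  tables <- tables[groups]
  battery <- config$battery
  if (is.null(battery)) battery <- default_battery(groups)
  for (b in battery)
    if (!b$parameter %in% .cp_par_names || length(b$groups) < 2L ||
        !all(b$groups %in% groups))
      stop("invalid battery entry: each needs a model parameter and >= 2 ",
           "configured groups", call. = FALSE)
  options <- cp_fit_options(seed = config$seed)
  spec <- cp_model_spec(groups)

  message(sprintf("[aggregate] groups=%s n=%g",
                  paste(groups, collapse = ","),
                  sum(vapply(tables, function(t)
                    t$n_defect_tree + t$n_coop_tree, 0))))
  fit <- fit_cp(spec, tables, options)
  message(sprintf("[fit] G2(%d)=%.4f seed=%d elapsed=%.1fs", fit$df,
                  fit$g_squared, config$seed,
                  proc.time()[["elapsed"]] - t0))
  tests <- vector("list", length(battery))
  for (i in seq_along(battery)) {
    b <- battery[[i]]
    tests[[i]] <- tryCatch(
      cp_nested_test(spec, tables, b$parameter, b$groups, options),
      error = function(e)
        stop("test stage failed for ", b$parameter, " {",
             paste(b$groups, collapse = ","), "}: ", conditionMessage(e),
             call. = FALSE))
    names(tests)[i] <- paste0(b$parameter, ":",
                              paste(b$groups, collapse = "="))
  }
  message(sprintf("[battery] %d comparison(s) elapsed=%.1fs",
                  length(tests), proc.time()[["elapsed"]] - t0))
  cfg_txt <- paste(utils::capture.output(utils::str(
    config[c("groups", "battery", "alpha", "seed", "bonferroni")])),
    collapse = "\n")
  structure(
    list(fit = fit, tests = tests, tables = tables, battery = battery,
         alpha = config$alpha, bonferroni = config$bonferroni,
         provenance = list(
           config_hash = .fnv1a(cfg_txt),
           seed = config$seed,
           n_total = fit$n_total,
           package_version = as.character(utils::packageVersion("cpmpt")))),
    class = "cp_report"
  )
}

#' @export
print.cp_report <- function(x, ...) {
  cat("=== Cooperation-and-punishment analysis ===\n\nBase model\n")
  print(x$fit)
  cat("\nEquality tests (unadjusted", "p values)\n")
  m <- length(x$tests)
  for (i in seq_along(x$tests)) {
    t <- x$tests[[i]]
    extra <- if (x$bonferroni)
      sprintf("  [Bonferroni p = %s]", .fmt_p(min(1, t$p_value * m))) else ""
    cat(sprintf("  %-50s Delta G^2(%d) = %s, p = %s, w %s%s\n",
                paste0(t$parameter, " {",
                       paste(t$groups, collapse = " = "), "}"),
                t$df, .fmt_num(t$delta_g_squared, 2), .fmt_p(t$p_value),
                .fmt_w(t$w), extra))
  }
  cat(sprintf("\nprovenance: config %s, seed %d, version %s\n",
              x$provenance$config_hash, x$provenance$seed,
              x$provenance$package_version))
  invisible(x)
}

#' Serialize a report (full precision) to JSON
#'
#' @param report A [run_cp_analysis()] report.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cp_report <- function(report, path) {
  stopifnot(inherits(report, "cp_report"))
  fit <- report$fit
  out <- list(
    base_fit = list(
      estimates = as.data.frame(fit$estimates),
      standard_errors = as.data.frame(fit$se),
      g_squared = fit$g_squared, df = fit$df, p_value = fit$p_value,
      log_likelihood = fit$log_likelihood, converged = fit$converged,
      n_total = fit$n_total),
    tests = lapply(report$tests, function(t)
      list(parameter = t$parameter, groups = t$groups,
           delta_g_squared = t$delta_g_squared, df = t$df,
           p_value = t$p_value, w = t$w)),
    alpha = report$alpha,
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
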