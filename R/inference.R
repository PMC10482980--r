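# Multi-group maximum-likelihood estimation with cross-group equality
# constraints, G-squared goodness of fit, nested delta-G-squared tests with
# Cohen's w, and expected-information standard errors.
#
# Free parameters are optimized on the log-odds scale (boundary-safe), with
# a moment-based start plus seeded random restarts; estimates are reported
# on the probability scale.

#' Multi-group model specification
#'
#' One model instance per group, with optional equality constraints that
#' collapse a parameter to a single free value across a subset of groups
#' (the mechanism behind nested hypothesis tests).
#'
#' @param groups Character vector of unique group labels, in fixed order.
#' @param constraints List of constraints, each `list(parameter =, groups =)`
#'   naming one of the five model parameters and >= 2 of the group labels.
#'
#' @return Object of class `"cp_model_spec"`.
#' @export
#' @examples
#' cp_model_spec(c("control", "communication"))
#' cp_model_spec(c("a", "b"),
#'               constraints = list(list(parameter = "P_moral",
#'                                       groups = c("a", "b"))))
cp_model_spec <- function(groups, constraints = list()) {
  stopifnot(is.character(groups), length(groups) >= 1L,
            !anyDuplicated(groups))
  for (con in constraints) {
    if (!is.list(con) || !all(c("parameter", "groups") %in% names(con)))
      stop("each constraint must be list(parameter =, groups =)",
           call. = FALSE)
    if (!con$parameter %in% .cp_par_names)
      stop("unknown parameter \"", con$parameter, "\"; must be one of: ",
           paste(.cp_par_names, collapse = ", "), call. = FALSE)
    if (length(con$groups) < 2L || !all(con$groups %in% groups))
      stop("constraint on \"", con$parameter,
           "\" must name >= 2 existing groups", call. = FALSE)
  }
  structure(list(groups = groups, constraints = constraints),
            class = "cp_model_spec")
}

# Map (group, parameter) cells to free-parameter indices. Equality
# constraints merge cells of one parameter across groups into one class.
.free_index <- function(spec) {
  G <- length(spec$groups)
  cls <- matrix(seq_len(G * 5L), nrow = G, ncol = 5L,
                dimnames = list(spec$groups, .cp_par_names))
  for (con in spec$constraints) {
    j <- match(con$parameter, .cp_par_names)
    rows <- match(con$groups, spec$groups)
    tgt <- min(cls[rows, j])
    cls[rows, j] <- tgt
  }
  uc <- sort(unique(as.vector(cls)))
  idx <- matrix(match(cls, uc), nrow = G,
                dimnames = dimnames(cls))
  labels <- character(length(uc))
  for (k in seq_along(uc)) {
    cells <- which(idx == k, arr.ind = TRUE)
    labels[k] <- paste0(.cp_par_names[cells[1, 2]], "[",
                        paste(spec$groups[cells[, 1]], collapse = "="), "]")
  }
  list(idx = idx, n_free = length(uc), labels = labels)
}

#' Fitting options
#'
#' @param n_restarts Number of seeded random starting points tried in
#'   addition to a moment-based start. Default 10.
#' @param seed Integer seed for the random restarts; fits are bit-identical
#'   given the same options. Default 42.
#' @param rel_tol Relative convergence tolerance on the log-likelihood.
#'   Default 1e-10.
#' @param max_iter Iteration cap per start. Default 500.
#' @return Object of class `"cp_fit_options"`.
#' @export
cp_fit_options <- function(n_restarts = 10L, seed = 42L,
                           rel_tol = 1e-10, max_iter = 500L) {
  stopifnot(n_restarts >= 0L, rel_tol > 0, max_iter > 0L)
  structure(list(n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed),
                 rel_tol = rel_tol, max_iter = as.integer(max_iter)),
            class = "cp_fit_options")
}

# run code with a temporary RNG state, restoring the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.P_CLIP <- 1e-12

# moment-based starting values for one group, on the probability scale
.moment_start <- function(table) {
  n <- table$counts
  safe_share <- function(a, b) {
    tot <- a + b
    if (tot <= 0) return(0.1)
    max(min(a / tot, 0.99), 0.01)
  }
  C0 <- safe_share(n[1] + n[2] + n[5] + n[6], n[3] + n[4] + n[7] + n[8])
  b0 <- safe_share(n[5], n[6])
  detype <- function(p_punish) {           # invert p = P + (1 - P) b
    max(min((p_punish - b0) / (1 - b0), 0.95), 0.05)
  }
  c(C = C0,
    P_moral = detype(safe_share(n[1], n[2])),
    P_hypocritical = detype(safe_share(n[3], n[4])),
    P_antisocial = detype(safe_share(n[7], n[8])),
    b = max(min(b0, 0.95), 0.05))
}

# negative log-likelihood and its gradient on the log-odds scale
.make_objective <- function(idx, counts_mat, tree_n) {
  G <- nrow(idx)
  pos <- lapply(seq_len(G), function(g) which(counts_mat[g, ] > 0))
  negll <- function(x) {
    th <- stats::plogis(x)
    total <- 0
    for (g in seq_len(G)) {
      p <- pmax(.cp_probs_fast(th[idx[g, ]]), .P_CLIP)
      j <- pos[[g]]
      total <- total + sum(counts_mat[g, j] * log(p[j]))
    }
    -total
  }
  grad <- function(x) {
    th <- stats::plogis(x)
    gfree <- numeric(length(x))
    for (g in seq_len(G)) {
      thg <- th[idx[g, ]]
      p <- pmax(.cp_probs_fast(thg), .P_CLIP)
      J <- .cp_jac_fast(thg)
      w <- counts_mat[g, ] / p
      gtheta <- as.vector(crossprod(J, w))
      gfree[idx[g, ]] <- gfree[idx[g, ]] + gtheta
    }
    -(gfree * th * (1 - th))
  }
  list(negll = negll, grad = grad)
}

.g_squared <- function(counts_mat, expected_mat) {
  obs <- as.vector(counts_mat)
  exp_ <- pmax(as.vector(expected_mat), .P_CLIP)
  pos <- obs > 0
  2 * sum(obs[pos] * log(obs[pos] / exp_[pos]))
}

#' Fit the cooperation-and-punishment model by maximum likelihood
#'
#' Maximizes the summed multinomial log-likelihood over all groups, with
#' any equality constraints of `spec` collapsing the equated parameters to
#' a single free value. Reports estimates, expected-information standard
#' errors, the likelihood-ratio goodness-of-fit statistic
#' `G^2 = 2 * sum(obs * log(obs / expected))` and its chi-square p value at
#' `df = 6 * n_groups - n_free_parameters` (each group contributes two
#' trees with three independent category probabilities each).
#'
#' @param spec A [cp_model_spec()].
#' @param tables Named list of [cp_freq_table()] objects, one per group in
#'   `spec` (names must cover `spec$groups`); both tree totals must be
#'   positive in every group.
#' @param options A [cp_fit_options()].
#'
#' @return Object of class `"cp_fit"` with elements `estimates` (group x
#'   parameter matrix), `se` (same shape; `NA` where the estimate is at the
#'   boundary), `g_squared`, `df`, `p_value`, `log_likelihood`,
#'   `converged`, `n_total` (total test decisions across groups),
#'   `expected` (group x category expected counts), plus the inputs.
#' @export
#' @examples
#' th <- cp_theta(0.6, 0.4, 0.2, 0.1, 0.1)
#' tab <- cp_freq_table(expected_counts(th, 1000, 1000))
#' fit <- fit_cp(cp_model_spec("g1"), list(g1 = tab))
#' round(fit$estimates, 3)
fit_cp <- function(spec, tables, options = cp_fit_options()) {
  stopifnot(inherits(spec, "cp_model_spec"),
            inherits(options, "cp_fit_options"))
  if (is.null(names(tables)) || !all(spec$groups %in% names(tables)))
    stop("`tables` must be a named list covering every group in `spec`",
         call. = FALSE)
  tables <- tables[spec$groups]
  for (g in spec$groups) {
    tab <- tables[[g]]
    stopifnot(inherits(tab, "cp_freq_table"))
    if (tab$n_defect_tree <= 0 || tab$n_coop_tree <= 0)
      stop("group \"", g, "\" has an empty tree; both trees need ",
           "at least one test decision", call. = FALSE)
  }
  G <- length(spec$groups)
  fi <- .free_index(spec)
  counts_mat <- do.call(rbind, lapply(tables, function(t) t$counts))
  tree_n <- cbind(defect = vapply(tables, `[[`, 0, "n_defect_tree"),
                  coop = vapply(tables, `[[`, 0, "n_coop_tree"))
  obj <- .make_objective(fi$idx, counts_mat, tree_n)

  # starting points: moment start, then seeded random restarts
  moment <- matrix(NA_real_, G, 5L)
  for (g in seq_len(G)) moment[g, ] <- .moment_start(tables[[g]])
  x0_moment <- numeric(fi$n_free)
  for (k in seq_len(fi$n_free)) {
    cells <- which(fi$idx == k, arr.ind = TRUE)
    x0_moment[k] <- stats::qlogis(mean(moment[cells]))
  }
  starts <- list(x0_moment)
  if (options$n_restarts > 0L) {
    rand <- .with_seed(options$seed,
                       matrix(stats::runif(options$n_restarts * fi$n_free,
                                           0.02, 0.98),
                              nrow = options$n_restarts))
    for (r in seq_len(options$n_restarts))
      starts[[r + 1L]] <- stats::qlogis(rand[r, ])
  }

  best <- NULL
  for (x0 in starts) {
    res <- tryCatch(
      stats::nlminb(x0, obj$negll, gradient = obj$grad,
                    lower = rep(-30, fi$n_free), upper = rep(30, fi$n_free),
                    control = list(rel.tol = options$rel_tol,
                                   iter.max = options$max_iter,
                                   eval.max = 4L * options$max_iter)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    stop("optimization failed from every starting point", call. = FALSE)
  converged <- best$convergence == 0L

  x_hat <- best$par
  th_free <- stats::plogis(x_hat)
  estimates <- matrix(th_free[fi$idx], nrow = G,
                      dimnames = list(spec$groups, .cp_par_names))
  expected <- matrix(NA_real_, G, 8L,
                     dimnames = list(spec$groups, cp_category_labels()))
  for (g in seq_len(G))
    expected[g, ] <- expected_counts(estimates[g, ], tree_n[g, 1], tree_n[g, 2])

  g2 <- .g_squared(counts_mat, expected)
  df <- 6L * G - fi$n_free
  se_free <- .se_free(fi, estimates, tree_n)
  se <- matrix(se_free[fi$idx], nrow = G,
               dimnames = dimnames(estimates))

  structure(
    list(estimates = estimates, se = se,
         g_squared = g2, df = df,
         p_value = stats::pchisq(g2, df, lower.tail = FALSE),
         log_likelihood = -best$objective,
         converged = converged,
         n_total = sum(tree_n),
         expected = expected,
         free_labels = fi$labels, n_free = fi$n_free,
         spec = spec, tables = tables, options = options),
    class = "cp_fit"
  )
}

# expected Fisher information over the free parameters (probability scale),
# inverted to standard errors; boundary estimates get NA
.se_free <- function(fi, estimates, tree_n, boundary_tol = 1e-6) {
  K <- fi$n_free
  info <- matrix(0, K, K)
  G <- nrow(estimates)
  for (g in seq_len(G)) {
    thg <- estimates[g, ]
    p <- category_probabilities(thg)
    J <- cp_prob_jacobian(thg)
    Ncat <- c(rep(tree_n[g, 1], 4L), rep(tree_n[g, 2], 4L))
    w <- ifelse(p > .P_CLIP, Ncat / p, 0)
    Ig <- crossprod(J, J * w)                 # 5 x 5
    map <- fi$idx[g, ]
    for (a in 1:5) for (b in 1:5)
      info[map[a], map[b]] <- info[map[a], map[b]] + Ig[a, b]
  }
  at_boundary <- logical(K)
  for (k in seq_len(K)) {
    vals <- estimates[fi$idx == k]
    at_boundary[k] <- any(vals < boundary_tol | vals > 1 - boundary_tol)
  }
  se <- rep(NA_real_, K)
  keep <- which(!at_boundary)
  if (length(keep)) {
    V <- tryCatch(solve(info[keep, keep, drop = FALSE]),
                  error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)
      se[keep] <- ifelse(d >= 0, sqrt(d), NA_real_)
    }
  }
  se
}

#' Expected-information standard errors at given estimates
#'
#' Square roots of the diagonal of the inverse expected Fisher information
#' of the multinomial likelihood, evaluated at `estimates`. Parameters
#' estimated at the boundary of [0, 1] get `NA` (the usual asymptotics do
#' not apply there).
#'
#' @param spec A [cp_model_spec()].
#' @param tables Named list of [cp_freq_table()] per group.
#' @param estimates Group x parameter matrix on the probability scale (as
#'   in a `cp_fit`), or a single [cp_theta()] for a one-group spec.
#' @return Group x parameter matrix of standard errors.
#' @export
cp_standard_errors <- function(spec, tables, estimates) {
  stopifnot(inherits(spec, "cp_model_spec"))
  tables <- tables[spec$groups]
  G <- length(spec$groups)
  if (inherits(estimates, "cp_theta") || is.null(dim(estimates)))
    estimates <- matrix(.as_theta(estimates), nrow = G, ncol = 5L,
                        byrow = TRUE,
                        dimnames = list(spec$groups, .cp_par_names))
  fi <- .free_index(spec)
  tree_n <- cbind(vapply(tables, `[[`, 0, "n_defect_tree"),
                  vapply(tables, `[[`, 0, "n_coop_tree"))
  se_free <- .se_free(fi, estimates, tree_n)
  matrix(se_free[fi$idx], nrow = G, dimnames = dimnames(estimates))
}

#' Cohen's effect size w for a chi-square-distributed statistic
#'
#' `w = sqrt(statistic / n_total)`, where `n_total` is the total number of
#' observations entering the fitted model (all test decisions of all
#' groups, not just the groups being compared).
#'
#' @param delta_g_squared Non-negative test statistic.
#' @param n_total Positive total observation count.
#' @return Scalar effect size.
#' @export
#' @examples
#' effect_size_w(5.11, 203 * 20)  # 0.0355 -> prints as 0.04
effect_size_w <- function(delta_g_squared, n_total) {
  stopifnot(is.numeric(delta_g_squared), is.numeric(n_total))
  if (delta_g_squared < 0)
    stop("`delta_g_squared` must be non-negative", call. = FALSE)
  if (n_total <= 0)
    stop("`n_total` must be positive", call. = FALSE)
  sqrt(delta_g_squared / n_total)
}

#' Nested likelihood-ratio test of a cross-group equality constraint
#'
#' Fits the base model given by `spec` and the restricted model with one
#' added equality constraint, and compares them:
#' `delta G^2 = G^2(restricted) - G^2(base)`, chi-square distributed under
#' the restriction with `df = length(groups) - 1`. Effect size
#' `w = sqrt(delta G^2 / n_total)` uses the total test decisions of all
#' groups in the model. Tiny negative differences (optimizer noise, up to
#' 1e-6) are clipped to zero; anything more negative is an error.
#'
#' @param spec A [cp_model_spec()] (the base model).
#' @param tables Named list of [cp_freq_table()] per group.
#' @param parameter One of `"C"`, `"P_moral"`, `"P_hypocritical"`,
#'   `"P_antisocial"`, `"b"`.
#' @param groups Groups (>= 2) across which `parameter` is equated; default
#'   all groups of `spec`.
#' @param options A [cp_fit_options()].
#'
#' @return Object of class `"cp_test"` with `delta_g_squared`, `df`,
#'   `p_value`, `w`, `parameter`, `groups`, and the two fits
#'   (`fit_base`, `fit_restricted`).
#' @export
cp_nested_test <- function(spec, tables, parameter,
                           groups = spec$groups,
                           options = cp_fit_options()) {
  constraint <- list(parameter = parameter, groups = groups)
  base_fi <- .free_index(spec)
  restr_spec <- cp_model_spec(spec$groups,
                              c(spec$constraints, list(constraint)))
  restr_fi <- .free_index(restr_spec)
  df <- base_fi$n_free - restr_fi$n_free
  if (df <= 0L)
    stop("constraint on \"", parameter,
         "\" is already implied by the model specification", call. = FALSE)

  fit_base <- fit_cp(spec, tables, options)
  fit_restricted <- fit_cp(restr_spec, tables, options)

  dg2 <- fit_restricted$g_squared - fit_base$g_squared
  if (dg2 < 0) {
    if (dg2 < -1e-6)
      stop(sprintf(
        "restricted model fit better than the base model (delta G^2 = %.3g); %s",
        dg2, "the base fit likely did not reach its maximum"), call. = FALSE)
    dg2 <- 0
  }
  structure(
    list(delta_g_squared = dg2, df = df,
         p_value = stats::pchisq(dg2, df, lower.tail = FALSE),
         w = effect_size_w(dg2, fit_base$n_total),
         parameter = parameter, groups = groups,
         n_total = fit_base$n_total,
         converged = fit_base$converged && fit_restricted$converged,
         fit_base = fit_base, fit_restricted = fit_restricted),
    class = "cp_test"
  )
}

#' @export
print.cp_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cooperation-and-punishment model fit (%d group%s)\n",
              nrow(x$estimates), if (nrow(x$estimates) > 1) "s" else ""))
  est <- round(x$estimates, digits)
  se <- round(x$se, digits)
  out <- matrix(paste0(format(est), " (", format(se), ")"),
                nrow = nrow(est), dimnames = dimnames(est))
  print(noquote(out))
  cat(sprintf("G^2(%d) = %s, p = %s; n = %g decisions%s\n",
              x$df, .fmt_num(x$g_squared, 2), .fmt_p(x$p_value),
              x$n_total,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
print.cp_test <- function(x, ...) {
  cat(sprintf("Equality of %s across {%s}: Delta G^2(%d) = %s, p = %s, w %s\n",
              x$parameter, paste(x$groups, collapse = ", "), x$df,
              .fmt_num(x$delta_g_squared, 2), .fmt_p(x$p_value),
              .fmt_w(x$w)))
  invisible(x)
}
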