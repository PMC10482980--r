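# Trial-level simulator under the model's data-generating process, matching
# the study design: 26 rounds per participant (first 6 training), partner
# behavior preprogrammed half cooperating / half defecting, trials in
# random order, punishment drawn by traversing the matching tree branch.
# Plus a parameter-recovery harness for the whole estimation stack.

#' Design of one between-subjects group
#'
#' @param label Group label.
#' @param theta Generating [cp_theta()] for the group.
#' @param n_participants Number of participants (>= 1).
#' @return Object of class `"cp_group_design"`.
#' @export
group_design <- function(label, theta, n_participants) {
  stopifnot(is.character(label), length(label) == 1L, n_participants >= 1)
  structure(list(label = label, theta = .as_theta(theta),
                 n_participants = as.integer(n_participants)),
            class = "cp_group_design")
}

#' Per-participant trial schedule
#'
#' Defaults reproduce the study design: 26 trials of which the first 6 are
#' training, with partners split half cooperating / half defecting overall
#' (3/3 in training, 10/10 in the test phase) and trial order randomized
#' per participant.
#'
#' @param n_training Training trials (excluded from all modeling).
#'   Default 6, split as evenly as possible between partner behaviors.
#' @param n_test_defect,n_test_coop Test trials with defecting and
#'   cooperating partners. Defaults 10 and 10.
#' @return Object of class `"cp_schedule"`.
#' @export
trial_schedule <- function(n_training = 6L, n_test_defect = 10L,
                           n_test_coop = 10L) {
  stopifnot(n_training >= 0L, n_test_defect >= 1L, n_test_coop >= 1L)
  structure(list(n_training = as.integer(n_training),
                 n_test_defect = as.integer(n_test_defect),
                 n_test_coop = as.integer(n_test_coop)),
            class = "cp_schedule")
}

# deterministic per-participant seed stream: participant j of design d gets
# a seed derived from (seed, d, j) only, so adding participants or groups
# never reshuffles earlier ones
.participant_seed <- function(seed, design_idx, j) {
  (abs(seed) + design_idx * 100000003 + j * 7919) %% 2147483647 + 1
}

#' Simulate trial-level game logs under the model
#'
#' For each participant, partner behaviors follow the schedule in a
#' randomized order; the participant cooperates with probability `C` on
#' every trial; punishment is drawn by traversing the matching tree branch
#' (type-specific punishment probability first, then the unspecific bias
#' `b`); punished trials get an investment drawn uniformly from
#' `1..max_punishment`. Training trials are flagged and carry simulated
#' behavior too, but are excluded from modeling by [aggregate_trials()].
#'
#' @param designs A [group_design()] or list of them.
#' @param schedule A [trial_schedule()].
#' @param seed Integer master seed. Each participant's stream is derived
#'   from it by a fixed offset, so logs are fully reproducible and growing
#'   a group appends participants without changing existing rows.
#' @param rules A [cp_rules()]; sets the punishment-investment range.
#' @param partner_punishes_defection If `TRUE`, partners punish the
#'   participant's unilateral defection with a uniform 1..`max_punishment`
#'   investment (the online variant's punish-back); recorded in a
#'   `partner_punish_invest` column for payoff bookkeeping only.
#'
#' @return Trial-log data.frame (canonical columns of [write_trial_log()]),
#'   with a `"manifest"` attribute recording designs, schedule and seed.
#' @export
#' @examples
#' d <- group_design("g1", cp_theta(0.6, 0.4, 0.2, 0.1, 0.1), 5)
#' head(simulate_trials(d, seed = 1))
simulate_trials <- function(designs, schedule = trial_schedule(), seed,
                            rules = cp_rules(),
                            partner_punishes_defection = FALSE) {
  if (inherits(designs, "cp_group_design")) designs <- list(designs)
  stopifnot(length(designs) >= 1L, inherits(schedule, "cp_schedule"),
            is.numeric(seed))
  seed <- as.integer(seed)

  n_tr_def <- schedule$n_training %/% 2L
  n_tr_coop <- schedule$n_training - n_tr_def
  partner_base <- c(rep("defect", n_tr_def), rep("cooperate", n_tr_coop),
                    rep("defect", schedule$n_test_defect),
                    rep("cooperate", schedule$n_test_coop))
  phase_base <- c(rep("training", schedule$n_training),
                  rep("test", schedule$n_test_defect + schedule$n_test_coop))
  n_trials <- length(partner_base)

  pieces <- vector("list", sum(vapply(designs, `[[`, 0L, "n_participants")))
  k <- 0L
  global_id <- 0L
  for (d in seq_along(designs)) {
    des <- designs[[d]]
    th <- des$theta
    ptype <- c("defect:cooperate" = th[["P_moral"]],
               "defect:defect" = th[["P_hypocritical"]],
               "cooperate:cooperate" = 0,
               "cooperate:defect" = th[["P_antisocial"]])
    for (j in seq_len(des$n_participants)) {
      k <- k + 1L; global_id <- global_id + 1L
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(.participant_seed(seed, d, j))
      ord <- sample.int(n_trials)
      partner <- partner_base[ord]
      phase <- phase_base[ord]
      self <- ifelse(stats::runif(n_trials) < th[["C"]],
                     "cooperate", "defect")
      p_type <- unname(ptype[paste(partner, self, sep = ":")])
      u1 <- stats::runif(n_trials)
      u2 <- stats::runif(n_trials)
      punished <- u1 < p_type | (u1 >= p_type & u2 < th[["b"]])
      invest <- integer(n_trials)
      invest[punished] <- 1L + as.integer(
        floor(stats::runif(sum(punished)) * rules$max_punishment))
      partner_invest <- integer(n_trials)
      if (partner_punishes_defection) {
        back <- partner == "cooperate" & self == "defect"
        partner_invest[back] <- 1L + as.integer(
          floor(stats::runif(sum(back)) * rules$max_punishment))
      }
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
      pieces[[k]] <- data.frame(
        participant_id = sprintf("S%05d", global_id),
        group = des$label,
        trial = seq_len(n_trials),
        phase = phase,
        partner = partner,
        participant = self,
        punish_invest = invest,
        partner_punish_invest = partner_invest,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (!partner_punishes_defection) out$partner_punish_invest <- NULL
  attr(out, "manifest") <- list(
    designs = lapply(designs, function(d)
      list(label = d$label, theta = as.list(d$theta),
           n_participants = d$n_participants)),
    schedule = unclass(schedule),
    seed = seed,
    rules = unclass(rules),
    partner_punishes_defection = partner_punishes_defection)
  out
}

#' Parameter-recovery study for the estimation stack
#'
#' Repeatedly simulates one group under `theta_true`, aggregates to the
#' eight response categories, fits the model, and summarizes estimation
#' quality: per-parameter bias, root-mean-square error, and coverage of
#' nominal 95% Wald intervals (estimate +/- 1.96 SE on the probability
#' scale). Replicates whose fit did not converge or whose standard error
#' is undefined (boundary estimate) are counted and excluded from
#' coverage.
#'
#' @param theta_true Generating [cp_theta()]; all parameters should be
#'   interior (roughly within [0.05, 0.95]) for the Wald intervals to make
#'   sense.
#' @param n_participants Participants per replicate.
#' @param n_replicates Number of simulated replicates.
#' @param schedule A [trial_schedule()].
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param options [cp_fit_options()] passed to every fit.
#'
#' @return Object of class `"cp_recovery"`: matrices `estimates` and `se`
#'   (replicate x parameter), vectors `bias`, `rmse`, `coverage`, counts
#'   `n_nonconverged` and `n_boundary_se`, plus the inputs.
#' @export
parameter_recovery <- function(theta_true, n_participants, n_replicates,
                               schedule = trial_schedule(), seed = 1,
                               options = cp_fit_options()) {
  th <- .as_theta(theta_true)
  spec <- cp_model_spec("g")
  est <- se <- matrix(NA_real_, n_replicates, 5L,
                      dimnames = list(NULL, .cp_par_names))
  conv <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    log <- simulate_trials(group_design("g", th, n_participants),
                           schedule, seed = seed + r)
    tabs <- aggregate_trials(log)
    fit <- fit_cp(spec, tabs, options)
    est[r, ] <- fit$estimates["g", ]
    se[r, ] <- fit$se["g", ]
    conv[r] <- fit$converged
  }
  bias <- colMeans(est) - th
  rmse <- sqrt(colMeans(sweep(est, 2L, th)^2))
  covered <- abs(sweep(est, 2L, th)) <= 1.96 * se   # NA where SE undefined
  coverage <- colMeans(covered, na.rm = TRUE)
  structure(
    list(estimates = est, se = se, bias = bias, rmse = rmse,
         coverage = coverage,
         n_nonconverged = sum(!conv),
         n_boundary_se = colSums(is.na(se)),
         theta_true = th, n_participants = n_participants,
         n_replicates = n_replicates, seed = seed),
    class = "cp_recovery"
  )
}

#' @export
print.cp_recovery <- function(x, ...) {
  cat(sprintf(
    "Parameter recovery: %d replicates x %d participants (seed %g)\n",
    x$n_replicates, x$n_participants, x$seed))
  tab <- rbind(true = x$theta_true, bias = x$bias, rmse = x$rmse,
               coverage95 = x$coverage)
  print(round(tab, 4))
  if (x$n_nonconverged > 0)
    cat(sprintf("  %d replicate(s) did not converge\n", x$n_nonconverged))
  if (any(x$n_boundary_se > 0))
    cat(sprintf("  boundary SEs excluded from coverage: %s\n",
                paste(sprintf("%s=%d", .cp_par_names,
                              x$n_boundary_se), collapse = " ")))
  invisible(x)
}
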