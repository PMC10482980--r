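# Payoff rules and trial-level plumbing for the Prisoner's Dilemma game
# with a costly punishment option.

#' Payoff rules of the Prisoner's Dilemma game with costly punishment
#'
#' Encodes the economics of the paradigm: cooperation is a fixed investment
#' into a joint account, a bonus proportional to the total investment is
#' added, the account is split evenly, and punishment removes
#' `punishment_ratio` units from the partner per unit invested.
#'
#' Two stock configurations are used in practice: a laboratory variant in
#' cents with punishment investments 0--9, and an online variant in points
#' with punishment investments 0--3. Both share the same game payoffs; only
#' `max_punishment` differs.
#'
#' @param investment Currency units invested when cooperating (defection
#'   invests nothing). Default 30.
#' @param bonus_fraction Fraction of the summed investments added as a bonus
#'   before the joint account is split. Must lie strictly between 0 and 1.
#'   Default 1/3.
#' @param punishment_ratio Units deducted from the partner per unit the
#'   punisher invests. Default 10 (the 1:10 ratio).
#' @param max_punishment Largest punishment investment allowed per trial:
#'   9 for the cents variant, 3 for the points variant.
#' @param endowment Starting account balance (bookkeeping only; it never
#'   enters the statistical model). Default 400.
#'
#' @return An object of class `"cp_rules"`.
#' @export
#' @examples
#' cp_rules()              # laboratory variant, cents
#' cp_rules(max_punishment = 3, endowment = 100)  # online variant, points
cp_rules <- function(investment = 30, bonus_fraction = 1 / 3,
                     punishment_ratio = 10, max_punishment = 9,
                     endowment = 400) {
  stopifnot(investment > 0, punishment_ratio > 0, max_punishment > 0,
            endowment > 0)
  if (!(bonus_fraction > 0 && bonus_fraction < 1))
    stop("`bonus_fraction` must lie strictly in (0, 1)", call. = FALSE)
  structure(
    list(investment = investment, bonus_fraction = bonus_fraction,
         punishment_ratio = punishment_ratio,
         max_punishment = max_punishment, endowment = endowment),
    class = "cp_rules"
  )
}

#' @export
print.cp_rules <- function(x, ...) {
  cat("Prisoner's Dilemma payoff rules\n")
  cat(sprintf("  cooperate invests : %g\n", x$investment))
  cat(sprintf("  bonus fraction    : %.4g of summed investments\n",
              x$bonus_fraction))
  cat(sprintf("  punishment ratio  : 1:%g, investment 0..%g\n",
              x$punishment_ratio, x$max_punishment))
  cat(sprintf("  endowment         : %g\n", x$endowment))
  invisible(x)
}

.check_decision <- function(d) {
  if (!is.character(d) || length(d) != 1L ||
      !d %in% c("cooperate", "defect"))
    stop("decision must be \"cooperate\" or \"defect\"", call. = FALSE)
  d
}

#' Round payoff for a pair of decisions
#'
#' Both players' investments are pooled, a bonus of
#' `bonus_fraction * sum(investments)` is added, and each player receives
#' half of the joint account regardless of their own investment. The net
#' gain is that half-share minus the own investment. Under the default
#' rules this yields the classic ordering: mutual cooperation +10 each,
#' unilateral defection +20 for the defector and -10 for the cooperator,
#' mutual defection 0.
#'
#' @param d_self,d_partner `"cooperate"` or `"defect"`.
#' @param rules A [cp_rules()] object.
#'
#' @return Named numeric vector `c(self = ..., partner = ...)` of signed
#'   gains in currency units.
#' @export
#' @examples
#' round_payoff("cooperate", "cooperate")  # +10 / +10
#' round_payoff("cooperate", "defect")     # -10 / +20
round_payoff <- function(d_self, d_partner, rules = cp_rules()) {
  .check_decision(d_self)
  .check_decision(d_partner)
  inv_self <- if (d_self == "cooperate") rules$investment else 0
  inv_partner <- if (d_partner == "cooperate") rules$investment else 0
  pool <- inv_self + inv_partner
  share <- (pool + rules$bonus_fraction * pool) / 2
  c(self = share - inv_self, partner = share - inv_partner)
}

#' Deduction caused by a punishment investment
#'
#' @param invest Non-negative integer punishment investment.
#' @param rules A [cp_rules()] object; `invest` must not exceed
#'   `rules$max_punishment`.
#'
#' @return The deduction applied to the partner's account
#'   (`punishment_ratio * invest`).
#' @export
#' @examples
#' punishment_effect(2)  # 20 under the 1:10 ratio
punishment_effect <- function(invest, rules = cp_rules()) {
  stopifnot(is.numeric(invest), length(invest) == 1L)
  if (invest < 0 || invest > rules$max_punishment || invest != round(invest))
    stop(sprintf(
      "punishment investment must be an integer in [0, %g], got %g",
      rules$max_punishment, invest), call. = FALSE)
  rules$punishment_ratio * invest
}

#' The eight observable response categories
#'
#' One trial falls into one of eight categories: partner behavior
#' (defect-partner tree first) x participant behavior (cooperate first) x
#' punished (punished first). This fixed order is used everywhere counts or
#' probabilities are serialized, so tables are stable across runs.
#'
#' @return A data.frame with columns `partner`, `participant` (each
#'   `"cooperate"`/`"defect"`) and `punished` (logical), 8 rows.
#' @export
cp_categories <- function() {
  data.frame(
    partner = rep(c("defect", "cooperate"), each = 4L),
    participant = rep(rep(c("cooperate", "defect"), each = 2L), 2L),
    punished = rep(c(TRUE, FALSE), 4L),
    stringsAsFactors = FALSE
  )
}

#' Category labels in canonical order
#'
#' @return Character vector of 8 labels like `"defect:cooperate:punished"`.
#' @export
cp_category_labels <- function() {
  cc <- cp_categories()
  paste(cc$partner, cc$participant,
        ifelse(cc$punished, "punished", "not_punished"), sep = ":")
}

#' Map a test-phase trial to its response category
#'
#' Punishment is binarized: any positive investment counts as "punished".
#' The model is defined over punish/no-punish categories; the magnitude of
#' the investment affects payoffs only.
#'
#' @param partner,participant `"cooperate"` or `"defect"`.
#' @param punish_invest Non-negative punishment investment.
#' @param phase Trial phase; must be `"test"` (training trials are not
#'   modeled and are rejected).
#'
#' @return Integer index 1..8 into [cp_categories()], with the label as a
#'   name.
#' @export
categorize_trial <- function(partner, participant, punish_invest,
                             phase = "test") {
  if (!identical(phase, "test"))
    stop("only test-phase trials are categorized; got phase \"",
         phase, "\"", call. = FALSE)
  .check_decision(partner)
  .check_decision(participant)
  stopifnot(punish_invest >= 0)
  cc <- cp_categories()
  idx <- which(cc$partner == partner & cc$participant == participant &
                 cc$punished == (punish_invest > 0))
  names(idx) <- cp_category_labels()[idx]
  idx
}

# -- trial-log serialization ------------------------------------------------

.trial_log_cols <- c("participant_id", "group", "trial", "phase",
                     "partner", "participant", "punish_invest")

#' Write a trial log to CSV
#'
#' Columns: participant_id, group, trial, phase (training/test),
#' partner, participant (C/D), punish_invest. If the log carries a
#' simulation manifest (attribute `"manifest"`, attached by
#' [simulate_trials()]), it is written alongside as `<path>.manifest.json`.
#'
#' @param trials Trial-log data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  stopifnot(all(.trial_log_cols %in% names(trials)))
  out <- trials[, .trial_log_cols]
  out$partner <- ifelse(out$partner == "cooperate", "C", "D")
  out$participant <- ifelse(out$participant == "cooperate", "C", "D")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  manifest <- attr(trials, "manifest")
  if (!is.null(manifest))
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a canonical trial log written by [write_trial_log()]
#'
#' @param path CSV path.
#' @return Trial-log data.frame with decisions expanded to
#'   `"cooperate"`/`"defect"`.
#' @export
read_trial_log <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.trial_log_cols, names(x))
  if (length(missing))
    stop("trial log is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x$partner <- c(C = "cooperate", D = "defect")[x$partner]
  x$participant <- c(C = "cooperate", D = "defect")[x$participant]
  x
}

#' Account-balance trajectory for one participant's trials
#'
#' Pure bookkeeping of the money flow (endowment, round payoffs, own
#' punishment investments, deductions received from a punishing partner);
#' it never feeds the statistical model.
#'
#' @param trials Trial-log rows of a single participant, in play order.
#'   An optional `partner_punish_invest` column adds the partner's
#'   punish-back deductions.
#' @param rules A [cp_rules()] object.
#' @return Numeric vector of balances after each trial, starting from
#'   `rules$endowment`.
#' @export
account_trajectory <- function(trials, rules = cp_rules()) {
  stopifnot(length(unique(trials$participant_id)) <= 1L)
  n <- nrow(trials)
  gains <- numeric(n)
  for (i in seq_len(n)) {
    g <- round_payoff(trials$participant[i], trials$partner[i], rules)["self"]
    g <- g - trials$punish_invest[i]
    if (!is.null(trials$partner_punish_invest))
      g <- g - rules$punishment_ratio * trials$partner_punish_invest[i]
    gains[i] <- g
  }
  rules$endowment + cumsum(gains)
}
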