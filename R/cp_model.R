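# The multinomial cooperation-and-punishment model: two processing trees
# (defecting-partner tree, cooperating-partner tree), four observable
# categories each. Parameters are probabilities:
#   C               cooperation
#   P_moral         punishment after unilateral participant cooperation
#   P_hypocritical  punishment after mutual defection
#   P_antisocial    punishment after unilateral participant defection
#   b               unspecific punishment bias (residual branch in every
#                   path without type-specific punishment)

.cp_par_names <- c("C", "P_moral", "P_hypocritical", "P_antisocial", "b")

#' Parameter vector of the cooperation-and-punishment model
#'
#' @param C Probability of participant cooperation (same in both trees:
#'   decisions are simultaneous, so the participant's choice cannot depend
#'   on the partner's).
#' @param P_moral Probability of moral punishment after the participant's
#'   cooperation meets the partner's defection.
#' @param P_hypocritical Probability of hypocritical punishment after
#'   mutual defection.
#' @param P_antisocial Probability of antisocial punishment after the
#'   participant's defection meets the partner's cooperation.
#' @param b Unspecific punishment bias, applied whenever no type-specific
#'   punishment occurred (including after mutual cooperation).
#'
#' @return Named numeric vector of class `"cp_theta"`.
#' @export
#' @examples
#' cp_theta(C = 0.5, P_moral = 0.5, b = 0.1)
cp_theta <- function(C, P_moral = 0, P_hypocritical = 0,
                     P_antisocial = 0, b = 0) {
  th <- c(C = C, P_moral = P_moral, P_hypocritical = P_hypocritical,
          P_antisocial = P_antisocial, b = b)
  if (any(!is.finite(th)) || any(th < 0) || any(th > 1))
    stop("all model parameters must lie in [0, 1]", call. = FALSE)
  structure(th, class = "cp_theta")
}

.as_theta <- function(theta) {
  if (inherits(theta, "cp_theta")) return(unclass(theta))
  th <- unclass(theta)
  if (is.null(names(th))) {
    stopifnot(length(th) == 5L)
    names(th) <- .cp_par_names
  }
  th <- th[.cp_par_names]
  if (any(!is.finite(th)) || any(th < 0) || any(th > 1))
    stop("all model parameters must lie in [0, 1]", call. = FALSE)
  th
}

#' Category probabilities under the model
#'
#' Branch products of the two trees, in the canonical category order of
#' [cp_categories()]. In the defecting-partner tree a cooperating
#' participant punishes with probability `P_moral + (1 - P_moral) * b`
#' (type-specific punishment first, then the bias as a residual branch);
#' the other paths are analogous, and after mutual cooperation only the
#' bias can produce punishment.
#'
#' @param theta A [cp_theta()] vector (or any numeric vector of the five
#'   probabilities in canonical order).
#' @return Named numeric vector of length 8; each tree's four entries sum
#'   to 1.
#' @export
#' @examples
#' p <- category_probabilities(cp_theta(0.5, P_moral = 0.5, b = 0.5))
#' p["defect:cooperate:punished"]  # 0.5 * (0.5 + 0.5 * 0.5) = 0.375
category_probabilities <- function(theta) {
  th <- .as_theta(theta)
  C <- th[["C"]]; pm <- th[["P_moral"]]; ph <- th[["P_hypocritical"]]
  pa <- th[["P_antisocial"]]; b <- th[["b"]]
  p <- c(
    C * (pm + (1 - pm) * b),          # defect partner, cooperate, punished
    C * (1 - pm) * (1 - b),           # defect partner, cooperate, not
    (1 - C) * (ph + (1 - ph) * b),    # defect partner, defect, punished
    (1 - C) * (1 - ph) * (1 - b),     # defect partner, defect, not
    C * b,                            # coop partner, cooperate, punished
    C * (1 - b),                      # coop partner, cooperate, not
    (1 - C) * (pa + (1 - pa) * b),    # coop partner, defect, punished
    (1 - C) * (1 - pa) * (1 - b)      # coop partner, defect, not
  )
  names(p) <- cp_category_labels()
  p
}

# unvalidated, unnamed branch products for the optimizer's hot path;
# th is c(C, P_moral, P_hypocritical, P_antisocial, b)
.cp_probs_fast <- function(th) {
  C <- th[1L]; pm <- th[2L]; ph <- th[3L]; pa <- th[4L]; b <- th[5L]
  c(C * (pm + (1 - pm) * b), C * (1 - pm) * (1 - b),
    (1 - C) * (ph + (1 - ph) * b), (1 - C) * (1 - ph) * (1 - b),
    C * b, C * (1 - b),
    (1 - C) * (pa + (1 - pa) * b), (1 - C) * (1 - pa) * (1 - b))
}

# unnamed Jacobian for the hot path; rows = categories, cols = parameters
.cp_jac_fast <- function(th) {
  C <- th[1L]; pm <- th[2L]; ph <- th[3L]; pa <- th[4L]; b <- th[5L]
  am <- pm + (1 - pm) * b; ah <- ph + (1 - ph) * b; aa <- pa + (1 - pa) * b
  matrix(c(
    am,                 C * (1 - b),    0,                0,               C * (1 - pm),
    (1 - pm) * (1 - b), -C * (1 - b),   0,                0,               -C * (1 - pm),
    -ah,                0,              (1 - C) * (1 - b), 0,              (1 - C) * (1 - ph),
    -(1 - ph) * (1 - b), 0,             -(1 - C) * (1 - b), 0,             -(1 - C) * (1 - ph),
    b,                  0,              0,                0,               C,
    1 - b,              0,              0,                0,               -C,
    -aa,                0,              0,                (1 - C) * (1 - b), (1 - C) * (1 - pa),
    -(1 - pa) * (1 - b), 0,             0,                -(1 - C) * (1 - b), -(1 - C) * (1 - pa)
  ), nrow = 8L, byrow = TRUE)
}

# 8 x 5 Jacobian of the category probabilities with respect to theta
# (probability scale). Rows follow the canonical category order.
cp_prob_jacobian <- function(theta) {
  J <- .cp_jac_fast(.as_theta(theta))
  dimnames(J) <- list(cp_category_labels(), .cp_par_names)
  J
}

#' Frequency table of the eight response categories for one group
#'
#' @param counts Numeric vector of 8 non-negative integer counts in the
#'   canonical category order of [cp_categories()] (names, if present,
#'   must match [cp_category_labels()]).
#' @return Object of class `"cp_freq_table"`: the counts plus the two tree
#'   totals `n_defect_tree` (categories 1--4) and `n_coop_tree`
#'   (categories 5--8).
#' @export
#' @examples
#' cp_freq_table(c(30, 70, 10, 90, 5, 95, 15, 85))
cp_freq_table <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) == 8L)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be non-negative integers", call. = FALSE)
  counts <- round(counts)
  if (!is.null(names(counts)) &&
      !identical(names(counts), cp_category_labels()))
    counts <- counts[cp_category_labels()]
  counts <- as.numeric(counts)
  names(counts) <- cp_category_labels()
  structure(
    list(counts = counts,
         n_defect_tree = sum(counts[1:4]),
         n_coop_tree = sum(counts[5:8])),
    class = "cp_freq_table"
  )
}

#' @export
print.cp_freq_table <- function(x, ...) {
  cc <- cp_categories()
  cc$count <- x$counts
  cat(sprintf("Response-category counts (defect tree n = %g, coop tree n = %g)\n",
              x$n_defect_tree, x$n_coop_tree))
  print(cc, row.names = FALSE)
  invisible(x)
}

#' Write / read a frequency table as an 8-row CSV
#'
#' Columns partner, participant, punished, count, in canonical order;
#' round-trips losslessly.
#'
#' @param table A [cp_freq_table()].
#' @param path CSV path.
#' @return `path` (write) or the reconstructed `cp_freq_table` (read).
#' @export
write_freq_table <- function(table, path) {
  stopifnot(inherits(table, "cp_freq_table"))
  cc <- cp_categories()
  cc$count <- table$counts
  utils::write.csv(cc, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_freq_table
#' @export
read_freq_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("partner", "participant", "punished", "count") %in% names(x)),
            nrow(x) == 8L)
  key <- paste(x$partner, x$participant,
               ifelse(x$punished, "punished", "not_punished"), sep = ":")
  counts <- x$count[match(cp_category_labels(), key)]
  if (any(is.na(counts)))
    stop("frequency-table CSV does not contain the 8 canonical categories",
         call. = FALSE)
  cp_freq_table(counts)
}

#' Multinomial log-likelihood of a frequency table
#'
#' `sum(count * log(prob))` over the eight categories, with `0 * log(0)`
#' defined as 0. Returns `-Inf` exactly when a category with a positive
#' count has probability 0.
#'
#' @param theta A [cp_theta()] vector.
#' @param table A [cp_freq_table()].
#' @return Scalar log-likelihood (up to the multinomial coefficient, which
#'   does not depend on `theta`).
#' @export
cp_loglik <- function(theta, table) {
  stopifnot(inherits(table, "cp_freq_table"))
  p <- category_probabilities(theta)
  n <- table$counts
  pos <- n > 0
  if (any(pos & p == 0)) return(-Inf)
  sum(n[pos] * log(p[pos]))
}

#' Expected category counts under the model
#'
#' @param theta A [cp_theta()] vector.
#' @param n_defect_tree,n_coop_tree Total trials in the defecting-partner
#'   and cooperating-partner trees.
#' @return Named numeric vector of 8 expected counts; each tree's entries
#'   sum to its total.
#' @export
expected_counts <- function(theta, n_defect_tree, n_coop_tree) {
  stopifnot(n_defect_tree >= 0, n_coop_tree >= 0)
  p <- category_probabilities(theta)
  c(p[1:4] * n_defect_tree, p[5:8] * n_coop_tree)
}
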