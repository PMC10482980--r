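# shared fixtures and independent oracles, built in code at test time

# theta whose category probabilities are multiples of 1/16, so expected
# counts are exact integers at tree totals divisible by 16
theta_dyadic <- function() cp_theta(0.5, 0.5, 0.25, 0.25, 0.5)

# frequency table whose counts equal the expected counts exactly
dyadic_table <- function(n_per_tree = 160) {
  stopifnot(n_per_tree %% 16 == 0)
  cp_freq_table(expected_counts(theta_dyadic(), n_per_tree, n_per_tree))
}

random_theta <- function(lo = 0.02, hi = 0.98) {
  cp_theta(runif(1, lo, hi), runif(1, lo, hi), runif(1, lo, hi),
           runif(1, lo, hi), runif(1, lo, hi))
}

random_table <- function(theta, n_defect = 200, n_coop = 200) {
  p <- category_probabilities(theta)
  cp_freq_table(c(stats::rmultinom(1, n_defect, p[1:4]),
                  stats::rmultinom(1, n_coop, p[5:8])))
}

# independent branch-process simulator: one uniform draw per latent branch,
# written directly from the tree definition (not via simulate_trials)
branch_process_freqs <- function(theta, n_per_tree) {
  th <- unclass(theta)
  draw_tree <- function(partner) {
    coop <- runif(n_per_tree) < th[["C"]]
    ptype <- if (partner == "defect")
      ifelse(coop, th[["P_moral"]], th[["P_hypocritical"]])
    else
      ifelse(coop, 0, th[["P_antisocial"]])
    u1 <- runif(n_per_tree); u2 <- runif(n_per_tree)
    punished <- u1 < ptype | (u1 >= ptype & u2 < th[["b"]])
    table(factor(paste(ifelse(coop, "cooperate", "defect"),
                       ifelse(punished, "punished", "not_punished"),
                       sep = ":"),
                 levels = c("cooperate:punished", "cooperate:not_punished",
                            "defect:punished", "defect:not_punished")))
  }
  c(draw_tree("defect"), draw_tree("cooperate")) / n_per_tree
}

# brute-force maximum of the log-likelihood on a regular parameter grid
# (step per dimension), computed by direct enumeration in chunks
grid_best_loglik <- function(table, step = 0.05, chunk = 250000L) {
  vals <- seq(0, 1, by = step)
  m <- length(vals)
  total <- m^5
  counts <- table$counts
  pos <- which(counts > 0)
  n_def <- table$n_defect_tree; n_coop <- table$n_coop_tree
  best <- -Inf
  start <- 1
  while (start <= total) {
    idx <- start:min(start + chunk - 1, total)
    i1 <- ((idx - 1) %% m) + 1
    i2 <- (((idx - 1) %/% m) %% m) + 1
    i3 <- (((idx - 1) %/% m^2) %% m) + 1
    i4 <- (((idx - 1) %/% m^3) %% m) + 1
    i5 <- (((idx - 1) %/% m^4) %% m) + 1
    C <- vals[i1]; pm <- vals[i2]; ph <- vals[i3]; pa <- vals[i4]
    b <- vals[i5]
    P <- cbind(C * (pm + (1 - pm) * b), C * (1 - pm) * (1 - b),
               (1 - C) * (ph + (1 - ph) * b), (1 - C) * (1 - ph) * (1 - b),
               C * b, C * (1 - b),
               (1 - C) * (pa + (1 - pa) * b), (1 - C) * (1 - pa) * (1 - b))
    ll <- rep(0, length(idx))
    for (j in pos) ll <- ll + counts[j] * log(P[, j])
    mx <- max(ll, na.rm = TRUE)
    if (mx > best) best <- mx
    start <- start + chunk
  }
  best
}
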