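# Small in-code fixtures shared across test files.

# Call matrix with named dimensions from a plain vector (rows = samples).
make_calls <- function(values, n_samples, assay_ids = NULL) {
  m <- matrix(values, nrow = n_samples, byrow = TRUE)
  colnames(m) <- if (is.null(assay_ids))
    sprintf("assay%03d", seq_len(ncol(m))) else assay_ids
  rownames(m) <- sprintf("S%03d", seq_len(n_samples))
  storage.mode(m) <- "integer"
  m
}

# One MSP measurement row; NA marks an absent value.
msp_row <- function(cq = 30, tm = 80, size_bp = 100, peak_height = 1) {
  data.frame(cq = cq, tm = tm, size_bp = size_bp, peak_height = peak_height)
}

# Independent log-rank oracle: O - E with hypergeometric variance summed
# over distinct event times, computed from first principles.
logrank_stat_oracle <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & g == 1L)
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1L)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Exhaustive two-sided Fisher oracle for 2x2 tables: sum of hypergeometric
# probabilities of all fixed-margin tables no more probable than observed.
fisher_2x2_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
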