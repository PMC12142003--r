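# Shared fixtures for the suite: small seeded scenarios and a recall helper.

tiny_config <- function(n = 120, seed = 7, ...) {
  scenario_config(n_orthologs = n, seed = seed, ...)
}

# Per-class recall of called against true labels, for label recovery checks.
class_recall <- function(calls, truth_labels, id_col = "pair_id") {
  truth <- truth_labels[calls[[id_col]]]
  tab <- table(truth = truth, called = calls$category)
  common <- intersect(rownames(tab), colnames(tab))
  rec <- vapply(rownames(tab), function(cl) {
    if (cl %in% colnames(tab)) tab[cl, cl] / sum(tab[cl, ]) else 0
  }, numeric(1))
  rec
}

# Independent brute-force BH step-up oracle (definition, not p.adjust).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o[m]] <- min(1, p[o[m]])
  if (m > 1)
    for (i in (m - 1):1) q[o[i]] <- min(q[o[i + 1]], min(1, p[o[i]] * m / i))
  q
}

# Independent hypergeometric enumeration oracle for 2x2 exact tests.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  if (N == 0) return(1)
  lo <- max(0, k - m2); hi <- min(k, m1)
  x <- lo:hi
  pr <- exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(N, k))
  sum(pr[pr <= pr[a - lo + 1] * (1 + 1e-7)])
}
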