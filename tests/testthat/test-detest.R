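test_that("TMM factors are 1 for depth-only differences and respond to composition bias", {
  set.seed(5)
  a <- rpois(500, 200)
  m <- cbind(A = a, B = a)
  rownames(m) <- sprintf("g%03d", 1:500)
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  # pure depth difference is absorbed by the library size, not the factor
  m2 <- cbind(A = a, B = 2 * a)
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-12)

  # 5% of genes 100x inflated in B: factor_B must drop below 1, in the
  # direction an untrimmed weighted mean oracle shows after masking them
  m3 <- cbind(A = a, B = a)
  m3[1:25, "B"] <- m3[1:25, "B"] * 100
  f <- tmm_factors(m3)
  expect_lt(f["B"] / f["A"], 1)
  p <- sweep(m3, 2, colSums(m3), "/")
  oracle_shift <- mean(log2(p[-(1:25), "B"] / p[-(1:25), "A"]))
  expect_lt(oracle_shift, 0)

  expect_warning(tmm_factors(cbind(A = a, B = 0 * a)), "all-zero")
})

test_that("TMM factors agree with the established implementation", {
  skip_if_not_installed("edgeR")
  set.seed(6)
  m <- matrix(rnbinom(600 * 5, mu = 2^runif(600 * 5, 3, 9), size = 10), 600, 5)
  rownames(m) <- sprintf("g%03d", 1:600)
  libs <- colSums(m) * runif(5, 0.8, 1.2)
  f_ref <- edgeR::calcNormFactors(edgeR::DGEList(m, lib.size = libs))$samples$norm.factors
  expect_equal(unname(tmm_factors(m, libs)), f_ref, tolerance = 1e-8)
})

test_that("dispersion estimation recovers the truth and falls back without replicates", {
  set.seed(7)
  n <- 2000
  mu <- 2^runif(n, 4, 9)
  pois <- sapply(1:6, function(j) rpois(n, mu))
  est0 <- estimate_dispersion(pois, rep(c("a", "b"), each = 3))
  expect_lte(est0$common, 0.01)

  nb <- sapply(1:6, function(j) rnbinom(n, mu = mu, size = 1 / 0.2))
  est <- estimate_dispersion(nb, rep(c("a", "b"), each = 3))
  expect_gte(est$common, 0.15)
  expect_lte(est$common, 0.25)
  expect_equal(length(est$tagwise), n)
  expect_true(all(est$tagwise >= 0))

  expect_warning(est1 <- estimate_dispersion(nb[, 1:2], c("a", "b")), "0.05")
  expect_equal(est1$common, 0.05)
  expect_error(estimate_dispersion(-nb[, 1:3], rep("a", 3)), "negative")
})

test_that("exact test matches binomial and enumeration oracles", {
  # symmetric mode: all outcomes qualify
  expect_equal(nb_exact_test(5, 5, 1, 1, 0), 1)
  # binomial two-tail: counts (0, 10) at p = 1/2
  expect_equal(nb_exact_test(0, 10, 1, 1, 0), 2 / 1024)
  expect_equal(nb_exact_test(0, 0, 1, 1, 0.1), 1)  # s = 0 convention

  # phi = 0 with equal group sizes equals the exact binomial two-tail
  set.seed(8)
  for (trial in 1:50) {
    s <- sample(300, 1); a <- sample(0:s, 1)
    pr <- dbinom(0:s, s, 0.5)
    oracle <- sum(pr[pr <= pr[a + 1] * (1 + 1e-7)])
    expect_equal(nb_exact_test(a, s - a, 2, 2, 0), oracle, tolerance = 1e-9)
  }

  # phi > 0: independent enumeration oracle over every split (lgamma form)
  nb_split_oracle <- function(sa, sb, na, nb, phi) {
    s <- sa + sb
    size_a <- na / phi; size_b <- nb / phi
    ma <- s * na / (na + nb); mb <- s - ma
    la <- lgamma(0:s + size_a) - lgamma(size_a) - lgamma(0:s + 1) +
      size_a * log(size_a / (size_a + ma)) + (0:s) * log(ma / (size_a + ma))
    lb <- rev(lgamma(0:s + size_b) - lgamma(size_b) - lgamma(0:s + 1) +
                size_b * log(size_b / (size_b + mb)) + (0:s) * log(mb / (size_b + mb)))
    pr <- exp(la + lb); pr <- pr / sum(pr)
    sum(pr[pr <= pr[sa + 1] * (1 + 1e-7)])
  }
  expect_equal(nb_exact_test(2, 14, 2, 2, 0.1), nb_split_oracle(2, 14, 2, 2, 0.1),
               tolerance = 1e-12)
  set.seed(9)
  for (trial in 1:25) {
    sa <- sample(0:80, 1); sb <- sample(0:80, 1)
    if (sa + sb == 0) next
    na <- sample(1:3, 1); nb_ <- sample(1:3, 1)
    phi <- runif(1, 0.01, 0.5)
    expect_equal(nb_exact_test(sa, sb, na, nb_, phi),
                 nb_split_oracle(sa, sb, na, nb_, phi), tolerance = 1e-12)
  }
  expect_error(nb_exact_test(1, 1, 1, 1, -0.1), ">= 0")
})

test_that("exact test agrees with the established doubletail implementation", {
  skip_if_not_installed("edgeR")
  set.seed(10)
  sa <- sample(50:500, 20); sb <- sample(50:500, 20)
  mine <- nb_exact_test(sa, sb, 2, 2, 0.1)
  # phi/n for the group sums maps to edgeR's per-observation dispersion
  ref <- edgeR::exactTestBySmallP(matrix(sa, ncol = 1), matrix(sb, ncol = 1),
                                  dispersion = 0.1 / 2)
  expect_equal(mine, as.vector(ref), tolerance = 1e-6)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)  # m = 1
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (trial in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("run_de handles self-contrasts, column order and planted signal", {
  set.seed(12)
  n <- 300
  mu <- 2^runif(n, 4, 9)
  m <- sapply(1:6, function(j) rnbinom(n, mu = mu, size = 1 / 0.05))
  dimnames(m) <- list(sprintf("g%03d", 1:n), paste0("c", 1:6))

  # duplicated columns: no fold change, nothing significant
  dup <- m[, c(1, 2, 3, 1, 2, 3)]
  colnames(dup) <- paste0("c", 1:6)
  de0 <- run_de(dup, 1:3, 4:6)
  expect_true(all(de0$log2fc == 0))
  expect_true(all(de0$fdr > 0.9))

  # invariant to column order within groups
  de1 <- run_de(m, c("c1", "c2", "c3"), c("c4", "c5", "c6"))
  de2 <- run_de(m, c("c3", "c1", "c2"), c("c6", "c4", "c5"))
  expect_equal(de1$pvalue, de2$pvalue)
  expect_equal(de1$log2fc, de2$log2fc)

  expect_error(run_de(m, 1:3, 3:6), "disjoint")

  # power: one gene with a true 4-fold change, phi = 0.05, 3 vs 3. Detection
  # is near-certain; the log2fc estimate has sd ~ sqrt(2 phi / n) / ln 2 ~
  # 0.26, so the +/- 0.5 window around 2 covers ~94% of repetitions.
  detected <- 0; in_window <- 0
  reps <- 200
  set.seed(13)
  for (r in seq_len(reps)) {
    mu_r <- 2^runif(80, 5, 8)
    base <- sapply(1:6, function(j) rnbinom(80, mu = mu_r, size = 1 / 0.05))
    base[1, 1:3] <- rnbinom(3, mu = 4 * mu_r[1], size = 1 / 0.05)
    rownames(base) <- sprintf("g%02d", 1:80)
    de <- run_de(base, 1:3, 4:6)
    if (de$fdr[1] < 0.05 && de$log2fc[1] > 1) detected <- detected + 1
    if (de$log2fc[1] > 1.5 && de$log2fc[1] < 2.5) in_window <- in_window + 1
  }
  expect_gte(detected / reps, 0.95)
  expect_gte(in_window / reps, 0.90)
})
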