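test_that("cpm scales by library size and columns sum to 1e6", {
  expect_equal(cpm(matrix(7), lib_sizes = 7)[1], 1e6)
  expect_equal(as.vector(cpm(matrix(c(1, 3), 2), lib_sizes = 4)),
               c(250000, 750000))
  set.seed(1)
  m <- matrix(rpois(1300, 50), 100, 13)
  rownames(m) <- sprintf("g%03d", 1:100)
  cp <- cpm(m)
  expect_equal(unname(colSums(cp)), rep(1e6, 13), tolerance = 1e-6)
  expect_error(cpm(m, lib_sizes = rep(0, 13)), "> 0")
})

test_that("expression filter uses a strict CPM threshold and a column count", {
  cp <- matrix(0, 3, 13, dimnames = list(c("kept", "dropped", "boundary"), NULL))
  cp["kept", 1:4] <- 3
  cp["dropped", 1:3] <- 3
  cp["boundary", ] <- 2  # exactly at the threshold: "higher than 2" fails
  expect_equal(filter_expressed(cp), "kept")

  # monotone in the threshold: lowering min_cpm never drops a kept gene
  set.seed(2)
  cp2 <- matrix(rexp(400, 1 / 3), 40, 10)
  rownames(cp2) <- sprintf("g%02d", 1:40)
  for (th in c(2, 1, 0.5))
    expect_true(all(filter_expressed(cp2, min_cpm = 2, min_columns = 3) %in%
                      filter_expressed(cp2, min_cpm = th, min_columns = 3)))
  expect_error(filter_expressed(cp2[, 1:2, drop = FALSE], min_columns = 4),
               "fewer")
})

test_that("mapping ambiguity classifies reads by MQ-positive species hits", {
  rec <- data.frame(
    read_id = c("r1", "r2", "r2", "r3", "r4", "r4"),
    species = c("cbr", "cbr", "cni", "cni", "cbr", "cbr"),
    mapq = c(30, 30, 12, 20, 0, 0))
  st <- mapping_ambiguity(rec)
  expect_equal(st$n_reads, 3)        # r4 is MQ-0 only and excluded
  expect_equal(st$n_ambiguous, 1)    # r2 hits both genomes
  expect_equal(st$n_assigned_cbr, 1)
  expect_equal(st$n_assigned_cni, 1)
  expect_equal(st$n_ambiguous + st$n_assigned_cbr + st$n_assigned_cni, st$n_reads)
  expect_error(mapping_ambiguity(transform(rec, species = "dog")),
               "unknown species")

  # constructed fixture: 1000 reads, 10 dual-mappers -> fraction 0.01,
  # against an independent per-read grouping oracle
  set.seed(3)
  ids <- sprintf("r%04d", 1:1000)
  single <- data.frame(read_id = ids, species = sample(c("cbr", "cni"), 1000, TRUE),
                       mapq = 30)
  dual <- data.frame(read_id = rep(ids[1:10], 2),
                     species = rep(c("cbr", "cni"), each = 10), mapq = 25)
  st2 <- mapping_ambiguity(rbind(single, dual))
  expect_equal(st2$ambiguous_fraction, 0.01)
  oracle <- tapply(rbind(single, dual)$species, rbind(single, dual)$read_id,
                   function(s) length(unique(s)))
  expect_equal(st2$n_ambiguous, sum(oracle == 2))
})

test_that("spearman_rho matches the average-rank definition and is rank-invariant", {
  x <- c(2, 5, 9, 11)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, rev(x)), -1)
  # tie case: Pearson of average ranks [1,2.5,2.5,4] vs [1,3,2,4] is
  # 4.5 / sqrt(4.5 * 5) (hand computation via the rank formula)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4)), 4.5 / sqrt(4.5 * 5))
  # independent oracle: Pearson on explicitly averaged ranks
  set.seed(4)
  a <- sample(20, 15, TRUE); b <- sample(20, 15, TRUE)
  expect_equal(spearman_rho(a, b), stats::cor(rank(a), rank(b)))
  # invariance under strictly monotone transforms
  expect_equal(spearman_rho(exp(a), b^3 + b), spearman_rho(a, b))
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("assemble_groups drops cross-haplotype counts and conserves hybrid totals", {
  cfg <- tiny_config(n = 60, seed = 13)
  ex <- simulate_ase_experiment(cfg)
  tab <- assemble_groups(ex$counts, ex$sample_sheet, ex$ortholog_map)
  expect_equal(ncol(tab$counts), 13)
  expect_equal(nrow(tab$counts), 60)

  # hybrid haplotype columns carry exactly the raw per-gene counts
  expect_equal(tab$counts[, "BN_cbr_1"],
               stats::setNames(ex$counts[ex$truth$cbr_gene, "BN_cbr_1"],
                               ex$truth$pair_id))

  # a parental sample's counts on the other species' haplotype rows are deleted
  contaminated <- ex$counts
  contaminated[ex$truth$cni_gene[1], "Cbr_1"] <- 999
  tab2 <- assemble_groups(contaminated, ex$sample_sheet, ex$ortholog_map)
  expect_equal(tab2$counts[1, "Cbr_1"], tab$counts[1, "Cbr_1"])

  # totals: BN_cbr + BN_cni column sums equal the raw BN totals
  bn_cols <- grep("^BN", colnames(ex$counts), value = TRUE)
  expect_equal(sum(tab$counts[, bn_cols]), sum(ex$counts[, bn_cols]))

  expect_error(assemble_groups(ex$counts, ex$sample_sheet[0, ], ex$ortholog_map),
               "empty")
  bad_map <- ex$ortholog_map
  bad_map$pair_id[2] <- bad_map$pair_id[1]
  expect_error(assemble_groups(ex$counts, ex$sample_sheet, bad_map), "duplicate")
})

test_that("hybrid_totals sums haplotype pairs and preserves parental columns", {
  cfg <- tiny_config(n = 40, seed = 19)
  ex <- simulate_ase_experiment(cfg)
  tab <- assemble_groups(ex$counts, ex$sample_sheet, ex$ortholog_map)
  tot <- hybrid_totals(tab)
  expect_equal(tot$counts[, "BN_1"],
               tab$counts[, "BN_cbr_1"] + tab$counts[, "BN_cni_1"])
  expect_equal(tot$counts[, "Cbr_2"], tab$counts[, "Cbr_2"])
  expect_equal(unname(tot$lib_sizes["NB_1"]),
               unname(tab$lib_sizes["NB_cbr_1"] + tab$lib_sizes["NB_cni_1"]))
  expect_setequal(unique(tot$groups), c("Cni", "Cbr", "BN", "NB"))
})
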