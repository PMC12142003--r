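test_that("configuration invariants are enforced", {
  expect_error(scenario_config(class_mix = c(no_change = 0.5)), "sum to 1")
  expect_error(scenario_config(dispersion = -0.1), ">= 0")
  expect_error(scenario_config(n_imprinted_maternal = -1), "non-negative")
  expect_error(scenario_config(class_mix = c(nonsense = 1)), "unknown inheritance class")
})

test_that("truth generation is deterministic and respects class-conditional rules", {
  cfg <- tiny_config(n = 200, seed = 17)
  t1 <- build_truth(cfg)
  t2 <- build_truth(cfg)
  expect_identical(t1, t2)

  # conserved class forces zero divergence, offset and allele ratio
  cons <- t1[t1$regulatory_bn == "conserved", ]
  expect_true(all(cons$inheritance_bn == "no_change"))
  expect_true(all(cons$d == 0 & cons$r_bn == 0 & cons$offset_bn == 0))

  # cis is defined as allele ratio equal to the parental ratio, in both hybrids
  cis <- t1[t1$regulatory_bn == "cis", ]
  expect_equal(cis$r_bn, cis$d)
  expect_equal(cis$r_nb, cis$d)
  expect_true(all(abs(cis$d) >= cfg$effect_size))

  # trans equalizes the allele ratio
  trans <- t1[t1$regulatory_bn == "trans", ]
  expect_true(all(trans$r_bn == 0) && all(abs(trans$d) >= cfg$effect_size))

  # additive genes sit at the parental log2 midpoint (before noise)
  add <- t1[t1$inheritance_bn == "additive", ]
  mid <- (log2(add$cpm_cbr) + log2(add$cpm_cni)) / 2
  expect_equal(log2(add$cpm_bn_total), mid, tolerance = 1e-9)

  # transgressive totals sit effect_size beyond the parental extreme
  over <- t1[t1$inheritance_bn == "overdominant", ]
  expect_equal(log2(over$cpm_bn_total),
               pmax(log2(over$cpm_cbr), log2(over$cpm_cni)) + cfg$effect_size)
  under <- t1[t1$inheritance_bn == "underdominant", ]
  expect_equal(log2(under$cpm_bn_total),
               pmin(log2(under$cpm_cbr), log2(under$cpm_cni)) - cfg$effect_size)

  # dominant genes match the named parent
  cbr_dom <- t1[t1$inheritance_bn == "cbr_dominant", ]
  expect_equal(cbr_dom$cpm_bn_total, cbr_dom$cpm_cbr)
})

test_that("degenerate all-conserved scenario has zero divergence everywhere", {
  cfg <- tiny_config(n = 50, class_mix = c(no_change = 1),
                     reg_mix = c(conserved = 1))
  tr <- build_truth(cfg)
  expect_true(all(tr$d == 0 & tr$r_bn == 0 & tr$r_nb == 0 &
                    tr$offset_bn == 0 & tr$offset_nb == 0))
})

test_that("infeasible mix combinations are rejected with the conflicting pair named", {
  expect_error(build_truth(tiny_config(class_mix = c(overdominant = 1),
                                       reg_mix = c(conserved = 1))),
               "conserved.*overdominant")
  expect_error(build_truth(tiny_config(class_mix = c(no_change = 1),
                                       reg_mix = c(cis = 1))),
               "cis.*no_change")
  expect_error(build_truth(tiny_config(class_mix = c(no_change = 0.5, additive = 0.5),
                                       reg_mix = c(cis = 0.5, trans = 0.5))),
               "no_change.*conserved")
})

test_that("counts are reproducible, non-negative integers in the 13-column layout", {
  cfg <- tiny_config(n = 80, seed = 17)
  e1 <- simulate_ase_experiment(cfg)
  e2 <- simulate_ase_experiment(cfg)
  expect_identical(e1$counts, e2$counts)
  expect_equal(ncol(e1$counts), 13)
  expect_true(all(e1$counts >= 0) && all(e1$counts == round(e1$counts)))
  expect_equal(nrow(e1$counts), 2 * cfg$n_orthologs)
  expect_setequal(e1$sample_sheet$group,
                  c("Cni", "Cbr", "BN_cbr", "BN_cni", "NB_cbr", "NB_cni"))
})

test_that("Poisson limit: sample mean across many replicate columns matches expectation", {
  # phi = 0 and no library-size noise make each column an independent Poisson
  # draw; with 200 parental replicates the mean must land within 3 SE.
  cfg <- scenario_config(n_orthologs = 5, class_mix = c(no_change = 1),
                         reg_mix = c(conserved = 1), dispersion = 0,
                         lib_size_cv = 0, lib_size_mean = 1e6,
                         mean_log2_expr_range = c(8, 8),
                         replicates = c(Cni = 200, Cbr = 2, BN = 2, NB = 2),
                         seed = 3)
  ex <- simulate_ase_experiment(cfg)
  cni_cols <- ex$sample_sheet$column_id[ex$sample_sheet$group == "Cni"]
  cnts <- ex$counts[ex$truth$cni_gene, cni_cols]
  expected <- 2^8  # CPM 256 at lib 1e6 = 256 counts
  se <- sqrt(expected / length(cni_cols))
  expect_true(all(abs(rowMeans(cnts) - expected) < 3 * se))
})

test_that("imprinted genes split hybrid counts by the imprint fraction", {
  cfg <- scenario_config(n_orthologs = 60, n_imprinted_maternal = 10,
                         n_imprinted_paternal = 10, dispersion = 0,
                         lib_size_cv = 0, seed = 11,
                         class_mix = c(no_change = 0.6, additive = 0.4),
                         reg_mix = c(conserved = 0.6, cis = 0.4))
  ex <- simulate_ase_experiment(cfg)
  tr <- ex$truth
  mat <- tr[tr$imprint == "maternal", ]
  # maternal allele is Cni in BN and Cbr in NB
  bn_cbr <- rowSums(ex$counts[mat$cbr_gene, grep("^BN_cbr", colnames(ex$counts))])
  bn_cni <- rowSums(ex$counts[mat$cni_gene, grep("^BN_cni", colnames(ex$counts))])
  frac <- bn_cni / (bn_cni + bn_cbr)
  expect_true(all(abs(frac - 0.9) < 0.05))
  nb_cbr <- rowSums(ex$counts[mat$cbr_gene, grep("^NB_cbr", colnames(ex$counts))])
  nb_cni <- rowSums(ex$counts[mat$cni_gene, grep("^NB_cni", colnames(ex$counts))])
  expect_true(all(abs(nb_cbr / (nb_cbr + nb_cni) - 0.9) < 0.05))
})

test_that("fixtures round-trip losslessly through the readers", {
  cfg <- tiny_config(n = 40, seed = 5)
  ex <- simulate_ase_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(ex, dir)
  expect_true(all(file.exists(paths)))

  counts_back <- hybridASE:::read_counts_tsv(paths["counts"])
  expect_equal(counts_back, ex$counts)
  truth_back <- read_tsv(paths["truth"])
  expect_equal(nrow(truth_back), cfg$n_orthologs)
  gmt_back <- read_gmt(paths["gene_sets"])
  expect_equal(length(gmt_back), length(ex$gene_sets))
  expect_equal(gmt_back[[1]], ex$gene_sets[[1]])
  expect_equal(length(readLines(paths["gene_sets"])), length(ex$gene_sets))
})
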