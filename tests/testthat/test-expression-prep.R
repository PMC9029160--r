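test_that("quantile normalisation matches the rank-mean oracle and is idempotent", {
  x <- tiny_expr(matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                        dimnames = list(c("a", "b", "c"), NULL)), 1, 1)
  qn <- quantile_normalize(x)
  expect_equal(unname(qn$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, 2]), c(2.5, 3.5, 4.5))

  # already-identical columns are unchanged
  same <- tiny_expr(matrix(c(3, 1, 2, 3, 1, 2), nrow = 3,
                           dimnames = list(c("a", "b", "c"), NULL)), 1, 1)
  expect_equal(quantile_normalize(same)$values, same$values)

  # defining property: column-wise sorted values pairwise equal; idempotent
  y <- noise_expr(50, 4, 4, seed = 11)
  q1 <- quantile_normalize(y)
  sorted <- apply(q1$values, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  q2 <- quantile_normalize(q1)
  expect_equal(q2$values, q1$values, tolerance = 1e-12)
})

test_that("log2 transform handles the pseudocount and round-trips", {
  v <- matrix(c(0, 3, 7, 1), nrow = 2, dimnames = list(c("a", "b"), NULL))
  x <- tiny_expr(v, 1, 1)
  lx <- log2_transform(x, pseudocount = 1)
  expect_equal(lx$values["a", 1], 0)       # log2(0 + 1)
  expect_equal(lx$values["b", 1], 2)       # log2(3 + 1)
  expect_identical(lx$scale, "log2")
  back <- 2^lx$values - 1
  expect_equal(back, v, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(log2_transform(lx), "already")
  expect_error(log2_transform(x, pseudocount = 0), "positive")
})

test_that("differential expression matches t.test and applies the gates", {
  # closed-form example: clear 2-unit separation on the log2 scale
  tum <- c(5, 5.1, 4.9, 5.0, 5.0)
  nor <- c(3, 3.1, 2.9, 3.0, 3.0)
  v <- rbind(gene1 = c(nor, tum), gene2 = rnorm(10, 4))
  samples <- c(sprintf("N%02d", 1:5), sprintf("T%02d", 1:5))
  colnames(v) <- samples
  group <- stats::setNames(rep(c("normal", "tumor"), each = 5), samples)
  st <- stats::setNames(rep("basal", 5), samples[6:10])
  x <- expression_matrix(v, group, st, scale = "log2")
  de <- differential_expression(x)[1, ]
  expect_equal(de$log2_fc, 2, tolerance = 1e-6)
  expect_lt(de$p_value, 0.001)
  expect_true(de$passes)

  # pooled t equals stats::t.test with var.equal on random data
  set.seed(42)
  y <- noise_expr(30, 6, 8, seed = 42)
  ly <- log2_transform(y)
  de2 <- differential_expression(ly)
  i <- 7
  ref <- t.test(ly$values[i, ly$group == "tumor"], ly$values[i, ly$group == "normal"],
                var.equal = TRUE)
  expect_equal(de2$t_statistic[i], unname(ref$statistic), tolerance = 1e-10)
  expect_equal(de2$p_value[i], ref$p.value, tolerance = 1e-10)
  # Welch flag reproduces the unequal-variance test
  de3 <- differential_expression(ly, welch = TRUE)
  refw <- t.test(ly$values[i, ly$group == "tumor"], ly$values[i, ly$group == "normal"])
  expect_equal(de3$p_value[i], refw$p.value, tolerance = 1e-10)

  # constant gene in both groups: t = 0, p = 1, never passes
  vz <- matrix(2, nrow = 2, ncol = 8, dimnames = list(c("a", "b"), NULL))
  vz[2, ] <- 2^rnorm(8)
  xz <- log2_transform(tiny_expr(vz, 4, 4))
  dez <- differential_expression(xz)
  expect_equal(dez$t_statistic[1], 0)
  expect_equal(dez$p_value[1], 1)
  expect_false(dez$passes[1])

  # significant p but sub-threshold fold change fails the FC gate
  set.seed(1)
  base <- rnorm(40, 5, 0.05)
  shift <- log2(1.8)
  vf <- 2^rbind(g = c(base[1:20], base[21:40] + shift))
  xf <- log2_transform(tiny_expr(vf, 20, 20))
  def <- differential_expression(xf)
  expect_lt(def$p_value, 0.001)
  expect_false(def$passes)

  expect_error(differential_expression(log2_transform(noise_expr(5, 1, 4, 1))),
               "at least 2")
})

test_that("passing set is monotone in both thresholds", {
  sim <- simulate_expression(sim_config(n_genes = 150, n_ncrna = 10,
                                        n_normal = 20, n_tumor = 25,
                                        subtype_proportions = c(basal = 0.5, luminal_A = 0.5),
                                        n_biclusters = 2,
                                        bicluster_gene_sizes = c(10, 10),
                                        bicluster_sample_sizes = c(8, 8),
                                        n_brokers = 0, n_module_ncrna = 2,
                                        n_free_de_ncrna = 2, n_de_extra = 20,
                                        seed = 3))
  x <- log2_transform(quantile_normalize(sim$expr))
  strict <- differential_expression(x, p_threshold = 0.001, fc_threshold = 2)
  loose_p <- differential_expression(x, p_threshold = 0.01, fc_threshold = 2)
  loose_f <- differential_expression(x, p_threshold = 0.001, fc_threshold = 1.5)
  expect_true(all(strict$gene_id[strict$passes] %in% loose_p$gene_id[loose_p$passes]))
  expect_true(all(strict$gene_id[strict$passes] %in% loose_f$gene_id[loose_f$passes]))
})

test_that("null simulation keeps the DE rate at its nominal level", {
  sim <- simulate_expression(sim_config(n_genes = 2000, n_ncrna = 0,
                                        n_normal = 30, n_tumor = 30,
                                        n_biclusters = 0,
                                        bicluster_gene_sizes = integer(),
                                        bicluster_sample_sizes = integer(),
                                        effect_size = 0, n_brokers = 0,
                                        n_module_ncrna = 0, n_free_de_ncrna = 0,
                                        n_de_extra = 0, seed = 7))
  x <- log2_transform(sim$expr)
  de <- differential_expression(x)
  # p-values uniform under the null
  expect_gt(ks.test(de$p_value, "punif")$p.value, 0.01)
  # fraction with p <= 0.001 inside the 99% binomial band around 0.001
  n_hit <- sum(de$p_value <= 0.001)
  band <- qbinom(c(0.005, 0.995), 2000, 0.001)
  expect_gte(n_hit, band[1])
  expect_lte(n_hit, band[2])
})

test_that("biotype partition buckets passing genes and recovers planted pseudogenes", {
  de <- data.frame(gene_id = c("a", "b", "c"),
                   biotype = c("protein_coding", "protein_coding", "pseudogene"),
                   passes = c(TRUE, FALSE, TRUE))
  part <- biotype_partition(de)
  expect_named(part, c("protein_coding", "pseudogene"))
  expect_equal(part$pseudogene, "c")
  # missing biotypes go to "unannotated", not dropped
  part2 <- biotype_partition(de, biotype = c(a = "protein_coding"))
  expect_equal(part2$unannotated, "c")
  expect_equal(biotype_partition(de[FALSE, ]), structure(list(), counts = integer()))

  sim <- simulate_expression(sim_config(n_genes = 300, n_ncrna = 50,
                                        n_normal = 30, n_tumor = 40,
                                        subtype_proportions = c(basal = 0.5, luminal_A = 0.5),
                                        n_biclusters = 2,
                                        bicluster_gene_sizes = c(15, 15),
                                        bicluster_sample_sizes = c(8, 8),
                                        effect_size = 3, n_brokers = 2,
                                        n_module_ncrna = 6, n_free_de_ncrna = 20,
                                        n_de_extra = 30, seed = 5))
  x <- log2_transform(quantile_normalize(sim$expr))
  de2 <- differential_expression(x)
  planted_nc <- intersect(sim$truth$de_gene_ids, grep("^NC", rownames(x$values), value = TRUE))
  recovered <- unlist(biotype_partition(de2)[c("pseudogene", "antisense", "lincRNA",
                                               "processed_transcript", "repeat")])
  expect_gte(mean(planted_nc %in% recovered), 0.9)
})

test_that("expression TSV round trip preserves values and metadata", {
  sim <- simulate_expression(sim_config(n_genes = 40, n_ncrna = 10, n_normal = 6,
                                        n_tumor = 8, n_biclusters = 0,
                                        bicluster_gene_sizes = integer(),
                                        bicluster_sample_sizes = integer(),
                                        n_brokers = 0, n_module_ncrna = 0,
                                        n_free_de_ncrna = 0, n_de_extra = 5, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_expression_tsv(sim$expr, dir)
  back <- read_expression_tsv(paths["matrix"], paths["meta"], paths["biotype"])
  expect_equal(back$values, sim$expr$values, tolerance = 1e-8)
  expect_equal(back$group, sim$expr$group)
  expect_equal(back$subtype, sim$expr$subtype)
  expect_equal(back$biotype, sim$expr$biotype)
})
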