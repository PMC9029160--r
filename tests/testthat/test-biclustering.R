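# A compact single-block benchmark used across several tests.
block_sim <- function(seed, n_genes = 200, block = 15, samp = 8) {
  simulate_expression(sim_config(
    n_genes = n_genes, n_ncrna = 0, n_normal = 20, n_tumor = 30,
    subtype_proportions = c(basal = 1), n_biclusters = 1,
    bicluster_gene_sizes = block, bicluster_sample_sizes = samp,
    effect_size = 3, n_brokers = 0, n_module_ncrna = 0,
    n_free_de_ncrna = 0, n_de_extra = 0, seed = seed))
}

test_that("an all-zero matrix yields no biclusters", {
  m <- matrix(0, 20, 10)
  expect_warning(out <- isa_run(m, n_seeds = 5, seed = 1), "constant")
  expect_length(out$biclusters, 0)
})

test_that("isa_run is deterministic and its fixed points are genuine", {
  sim <- block_sim(31)
  x <- log2_transform(quantile_normalize(sim$expr))
  a <- isa_run(x, n_seeds = 20, seed = 5)
  b <- isa_run(x, n_seeds = 20, seed = 5)
  expect_identical(lapply(a$biclusters, `[[`, "genes"),
                   lapply(b$biclusters, `[[`, "genes"))
  expect_gt(length(a$biclusters), 0)

  # re-applying one alternation step to a membership-converged bicluster
  # leaves the membership unchanged (correlation-converged fixed points are
  # allowed to drift slightly by construction)
  E <- x$values
  rs <- apply(E, 1, sd)
  Er <- (E - rowMeans(E)) / rs
  cs <- apply(E, 2, sd)
  Ec <- t((t(E) - colMeans(E)) / cs)
  strict <- Filter(function(b) b$converged_by == "membership", a$biclusters)
  expect_gt(length(strict), 0)
  bc <- strict[[1]]
  g <- numeric(nrow(E))
  g[match(bc$genes, rownames(E))] <- bc$gene_scores
  step <- ncbroker:::isa_iterate(Er, Ec, g, bc$gene_threshold, bc$sample_threshold, 3L)
  expect_setequal(step$genes, bc$genes)
  expect_setequal(step$samples, bc$samples)
})

test_that("a planted block is recovered and two disjoint blocks give two fixed points", {
  sim <- block_sim(7, n_genes = 500, block = 20, samp = 10)
  x <- log2_transform(quantile_normalize(sim$expr))
  bs <- isa_run(x, n_seeds = 25, seed = 2)
  tg <- sim$truth$bicluster_memberships[[1]]$genes
  jac <- max(vapply(bs$biclusters, function(b) {
    length(intersect(b$genes, tg)) / length(union(b$genes, tg))
  }, numeric(1)))
  expect_gte(jac, 0.8)

  sim2 <- simulate_expression(sim_config(
    n_genes = 250, n_ncrna = 0, n_normal = 20, n_tumor = 40,
    subtype_proportions = c(basal = 0.5, luminal_A = 0.5), n_biclusters = 2,
    bicluster_gene_sizes = c(18, 18), bicluster_sample_sizes = c(9, 9),
    effect_size = 3, n_brokers = 0, n_module_ncrna = 0,
    n_free_de_ncrna = 0, n_de_extra = 0, seed = 13))
  x2 <- log2_transform(quantile_normalize(sim2$expr))
  bs2 <- isa_run(x2, n_seeds = 40, seed = 3)
  best <- vapply(sim2$truth$bicluster_memberships, function(b) {
    max(vapply(bs2$biclusters, function(fp) {
      length(intersect(fp$genes, b$genes)) / length(union(fp$genes, b$genes))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(best >= 0.6))
})

test_that("robustness separates planted structure from noise and grows with effect", {
  sim <- block_sim(19, block = 20, samp = 10)
  x <- log2_transform(quantile_normalize(sim$expr))
  tum <- names(x$group)[x$group == "tumor"]
  bs <- isa_run(x, n_seeds = 20, seed = 4, samples = tum)
  bs <- filter_biclusters(bs, 10, 7)
  tg <- sim$truth$bicluster_memberships[[1]]$genes
  jac <- vapply(bs$biclusters, function(b) {
    length(intersect(b$genes, tg)) / length(union(b$genes, tg))
  }, numeric(1))
  bc <- bs$biclusters[[which.max(jac)]]
  rob <- isa_robustness(bc, x, n_shuffles = 5, seed = 8, samples = tum,
                        min_genes = 10, min_samples = 7)
  expect_gt(rob$ratio, 1)
  expect_error(isa_robustness(bc, x, n_shuffles = 0), "n_shuffles")

  # a pure-noise "bicluster" scores near the shuffled ceiling
  noise <- noise_expr(150, 15, 25, seed = 77)
  ln <- log2_transform(noise)
  bn <- isa_run(ln, n_seeds = 20, seed = 5)
  if (length(bn$biclusters)) {
    rn <- isa_robustness(bn$biclusters[[1]], ln, n_shuffles = 5, seed = 6)
    expect_lt(rn$ratio, 2)
  }

  # median robustness does not decrease when the effect doubles
  med_ratio <- function(es) {
    r <- vapply(1:5, function(i) {
      s <- simulate_expression(sim_config(
        n_genes = 150, n_ncrna = 0, n_normal = 15, n_tumor = 25,
        subtype_proportions = c(basal = 1), n_biclusters = 1,
        bicluster_gene_sizes = 15, bicluster_sample_sizes = 8,
        effect_size = es, n_brokers = 0, n_module_ncrna = 0,
        n_free_de_ncrna = 0, n_de_extra = 0, seed = 100 + i))
      xx <- log2_transform(quantile_normalize(s$expr))
      tum_i <- names(xx$group)[xx$group == "tumor"]
      b <- isa_run(xx, n_seeds = 15, seed = i, samples = tum_i)
      b <- filter_biclusters(b, 10, 7)
      if (!length(b$biclusters)) return(0)
      tg_i <- s$truth$bicluster_memberships[[1]]$genes
      j <- vapply(b$biclusters, function(fp) {
        length(intersect(fp$genes, tg_i)) / length(union(fp$genes, tg_i))
      }, numeric(1))
      rr <- isa_robustness(b$biclusters[[which.max(j)]], xx, n_shuffles = 3,
                           seed = i, samples = tum_i, min_genes = 10, min_samples = 7)
      min(rr$ratio, 50)
    }, numeric(1))
    median(r)
  }
  expect_gte(med_ratio(4), med_ratio(2) * 0.9)
})

test_that("size and robustness filters behave as documented", {
  fake <- structure(list(biclusters = list(
    list(genes = letters[1:8], samples = LETTERS[1:9], score = 5, robustness = 5,
         robustness_ratio = 3),
    list(genes = letters[1:12], samples = LETTERS[1:7], score = 7, robustness = 7,
         robustness_ratio = 0.5)
  ), gene_thresholds = 2, sample_thresholds = 1, n_seeds = 1, seed = 1),
  class = "ncb_biclusters")
  # 8 genes < 10: discarded
  expect_length(filter_biclusters(fake)$biclusters, 1)
  # zero thresholds: identity
  expect_length(filter_biclusters(fake, 0, 0, 0)$biclusters, 2)
  # robustness ratio filter
  expect_length(filter_biclusters(fake, 0, 0, 1, metric = "ratio")$biclusters, 1)
  empty <- structure(list(biclusters = list(), gene_thresholds = 2,
                          sample_thresholds = 1, n_seeds = 1, seed = 1),
                     class = "ncb_biclusters")
  expect_length(filter_biclusters(empty)$biclusters, 0)
})

test_that("subtype fractions sum to one, flag unlabeled samples, and find dominants", {
  bl <- list(list(genes = c("g1"), samples = c("T01", "T02", "T03", "N01")),
             list(genes = c("g2"), samples = c("T04", "T05")))
  subtype <- c(T01 = "basal", T02 = "basal", T03 = "luminal_A",
               T04 = "luminal_B", T05 = "luminal_B")
  group <- c(T01 = "tumor", T02 = "tumor", T03 = "tumor", T04 = "tumor",
             T05 = "tumor", N01 = "normal")
  fr <- subtype_fractions(bl, subtype, group = group)
  expect_equal(rowSums(as.matrix(fr[, 1:3])), c("#1" = 1, "#2" = 1), tolerance = 1e-9)
  expect_equal(fr$dominant_subtype, c("basal", "luminal_B"))
  expect_equal(fr$dominant_fraction, c(2 / 3, 1))
  expect_error(subtype_fractions(bl, subtype[-1], group = group), "T01")
})

test_that("printed fraction tables reproduce the published dominance calls", {
  tab <- published_fractions()
  expect_equal(tab["#1", "dominant_subtype"], "basal")
  expect_equal(tab["#1", "dominant_fraction"], 0.73)
  expect_equal(tab["#13", "dominant_subtype"], "normal_like")
  expect_equal(tab["#13", "dominant_fraction"], 0.57)

  strict <- select_signature_biclusters(tab, mode = "strict", threshold = 0.5)
  expect_setequal(strict$bicluster, c("#1", "#13"))

  top <- select_signature_biclusters(tab, mode = "top_per_subtype")
  got <- setNames(top$bicluster, top$subtype)
  expect_equal(got[["luminal_A"]], "#12")
  expect_equal(got[["luminal_B"]], "#6")
  expect_equal(got[["normal_like"]], "#13")
  expect_equal(got[["basal"]], "#1")

  # dominance can never exceed 1
  expect_equal(nrow(select_signature_biclusters(tab, "strict", threshold = 1.1)), 0)
  empty <- subtype_fraction_table(matrix(numeric(0), 0, 0))
  expect_equal(nrow(select_signature_biclusters(empty)), 0)
  # malformed printed rows are rejected
  expect_error(subtype_fraction_table(matrix(c(0.5, 0.4), 1)), "sum to 1")
})

test_that("one-subtype biclusters give one-hot rows", {
  bl <- list(list(genes = "g", samples = c("T1", "T2", "T3")))
  fr <- subtype_fractions(bl, c(T1 = "basal", T2 = "basal", T3 = "basal"))
  expect_equal(fr$dominant_fraction, 1)
  expect_equal(fr[["basal"]], 1)
})

test_that("gene-based composition mode counts genes against a gene map", {
  bl <- list(list(genes = c("g1", "g2", "g3", "g4"), samples = c("T1")))
  gmap <- c(g1 = "basal", g2 = "basal", g3 = "basal", g4 = "luminal_A")
  fr <- subtype_fractions(bl, gmap, by = "genes")
  expect_equal(fr$dominant_subtype, "basal")
  expect_equal(fr$dominant_fraction, 0.75)
  expect_error(subtype_fractions(bl, gmap[-1], by = "genes"), "g1")
})
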