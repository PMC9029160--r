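test_that("normalised MI obeys its defining conventions and the joint-table oracle", {
  set.seed(3)
  x <- rnorm(60)
  m <- rbind(a = x, b = x, c = rnorm(60), d = rep(1, 60))
  colnames(m) <- paste0("s", 1:60)
  M <- pairwise_mi(m, n_bins = 4)
  expect_equal(M["a", "b"], 1)                 # duplicated gene: MI 1, d 0
  expect_equal(M["a", "a"], 1)
  expect_equal(unname(M["d", ]), rep(0, 4))    # constant gene: MI 0 against all
  expect_true(isSymmetric(M))
  expect_true(all(M >= 0 & M <= 1))

  # MI from an explicit 3x3 joint count table equals direct enumeration
  counts <- matrix(c(20, 5, 2, 4, 18, 6, 1, 7, 27), 3, 3, byrow = TRUE)
  ix <- rep(rep(1:3, each = 3), times = as.vector(t(counts)))
  iy <- rep(rep(1:3, times = 3), times = as.vector(t(counts)))
  got <- ncbroker:::mi_from_bins(ix, iy, 3L)
  expect_equal(got, oracle_mi_from_table(counts), tolerance = 1e-12)
})

test_that("absolute Spearman correlation is rank-invariant and symmetric", {
  set.seed(9)
  x <- rnorm(100)
  m <- rbind(a = x, b = exp(x), c = rnorm(100))
  colnames(m) <- paste0("s", 1:100)
  C <- pairwise_correlation(m)
  expect_equal(C["a", "b"], 1)                 # monotone transform of x vs x
  expect_equal(C["a", "c"], C["c", "a"])
  # independent pairs stay weak on average
  set.seed(10)
  mm <- matrix(rnorm(30 * 100), 30, dimnames = list(paste0("g", 1:30), paste0("s", 1:100)))
  C2 <- pairwise_correlation(mm)
  expect_lt(mean(C2[upper.tri(C2)]), 0.15)
})

test_that("permutation null gives the add-one corrected p and its edge cases", {
  set.seed(5)
  x <- rnorm(80)
  m <- rbind(a = x, b = x + rnorm(80, 0, 1e-6), c = rep(2, 80), d = rnorm(80))
  colnames(m) <- paste0("s", 1:80)
  pn <- permutation_null(m, c("a", "b"), n_perm = 1000, seed = 1)
  expect_equal(pn$null_p, 1 / 1001)            # duplicated pair: minimum p
  expect_length(pn$null_samples, 1000)
  pc <- permutation_null(m, c("c", "d"), n_perm = 50, seed = 1)
  expect_equal(pc$observed, 0)
  expect_equal(pc$null_p, 1)
  expect_error(permutation_null(m, c("a", "d"), n_perm = 10), "n_perm")
})

test_that("bootstrap persistence is 1 for duplicated genes and deterministic", {
  set.seed(6)
  x <- rnorm(60)
  m <- rbind(a = x, b = x, c = rnorm(60), d = rnorm(60))
  colnames(m) <- paste0("s", 1:60)
  edges <- rbind(c("a", "b"), c("c", "d"))
  p1 <- rewiring_persistence(m, edges, mi_threshold = 0.3, n_randomizations = 50, seed = 2)
  p2 <- rewiring_persistence(m, edges, mi_threshold = 0.3, n_randomizations = 50, seed = 2)
  expect_identical(p1, p2)
  expect_equal(unname(p1[1]), 1)
  expect_lt(unname(p1[2]), 0.5)                # independent pair rarely re-appears
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(rewiring_persistence(m[, 1:5], edges, 0.3), "8 samples")
})

test_that("template network stores d = 1 - MI, honours alpha = 0, ignores gene order", {
  sim <- simulate_expression(sim_config(
    n_genes = 120, n_ncrna = 10, n_normal = 15, n_tumor = 45,
    subtype_proportions = c(basal = 1), n_biclusters = 2,
    bicluster_gene_sizes = c(12, 12), bicluster_sample_sizes = c(8, 8),
    n_brokers = 1, n_module_ncrna = 2, n_free_de_ncrna = 2,
    n_de_extra = 10, seed = 12))
  x <- log2_transform(sim$expr)
  genes <- names(sim$truth$module_assignments)
  genes <- genes[grepl("^G", genes)]
  ncr <- grep("^NC", rownames(x$values), value = TRUE)[1:6]
  net <- build_template_network(x, genes, ncr, n_perm = 400, n_boot = 50, seed = 3)
  expect_gt(igraph::ecount(net), 0)
  expect_equal(igraph::E(net)$distance, 1 - igraph::E(net)$mi, tolerance = 1e-12)
  expect_true(all(igraph::E(net)$persistence >= igraph::graph_attr(net, "min_persistence")))
  expect_false(igraph::any_loop(net))

  # order invariance of the edge set
  net2 <- build_template_network(x, rev(genes), rev(ncr), n_perm = 400,
                                 n_boot = 50, seed = 3)
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(net), key(net2))

  # alpha = 0: the add-one correction forbids any edge
  expect_warning(net0 <- build_template_network(x, genes, ncr, alpha = 0,
                                               n_perm = 100, n_boot = 10, seed = 3),
                 "no edge")
  expect_equal(igraph::ecount(net0), 0)
  expect_true(all(igraph::V(net0)$isolated))

  expect_error(build_template_network(x, character(), ncr), "empty gene list")
})

test_that("a planted broker keeps significant persistent edges into both modules", {
  sim <- simulate_expression(sim_config(
    n_genes = 150, n_ncrna = 8, n_normal = 20, n_tumor = 124,
    subtype_proportions = c(basal = 0.5, luminal_A = 0.5), n_biclusters = 2,
    bicluster_gene_sizes = c(20, 20), bicluster_sample_sizes = c(10, 10),
    n_brokers = 1, n_module_ncrna = 2, n_free_de_ncrna = 1,
    n_de_extra = 10, seed = 23))
  x <- log2_transform(sim$expr)
  ma <- sim$truth$module_assignments
  genes <- names(ma)[grepl("^G", names(ma))]
  broker <- sim$truth$broker_ids
  net <- build_template_network(x, genes, broker, n_perm = 500, n_boot = 60, seed = 4)
  nb <- igraph::neighbors(net, broker)$name
  mods <- unique(ma[intersect(nb, names(ma))])
  expect_gte(length(mods), 2)
})

test_that("independent-noise added to a gene does not raise its median MI", {
  set.seed(31)
  base <- rnorm(100)
  partner <- 0.7 * base + rnorm(100, 0, sqrt(1 - 0.49))
  deltas <- vapply(1:20, function(i) {
    noisy <- base + rnorm(100, 0, 1)
    m <- rbind(a = base, b = partner, an = noisy)
    colnames(m) <- paste0("s", 1:100)
    M <- pairwise_mi(m, n_bins = 4)
    M["an", "b"] - M["a", "b"]
  }, numeric(1))
  expect_lte(median(deltas), 0)
})

test_that("per-edge mode keeps the survivor rate at the null level", {
  # truly independent genes, raw per-edge alpha, no persistence gate
  set.seed(41)
  m <- matrix(rnorm(30 * 80), 30, dimnames = list(paste0("g", 1:30), paste0("s", 1:80)))
  samples <- colnames(m)
  group <- stats::setNames(rep(c("normal", "tumor"), each = 40), samples)
  x <- expression_matrix(2^m, group,
                         stats::setNames(rep("basal", 40), samples[41:80]),
                         scale = "linear")
  lx <- log2_transform(x)
  suppressWarnings(
    net <- build_template_network(lx, rownames(m)[1:20], rownames(m)[21:30],
                                  alpha = 0.05, min_persistence = 0,
                                  n_perm = 500, n_boot = 10, samples = "all",
                                  seed = 6, correction = "none"))
  rate <- igraph::ecount(net) / choose(30, 2)
  expect_lte(rate, 0.05 * 2)
})

test_that("network files round-trip through GraphML and edge-list TSV", {
  g <- igraph::make_graph(~ a - b, b - c)
  igraph::E(g)$mi <- c(0.8, 0.6)
  igraph::E(g)$distance <- 1 - igraph::E(g)$mi
  igraph::E(g)$null_p <- c(0.001, 0.002)
  igraph::E(g)$persistence <- c(1, 0.9)
  igraph::V(g)$biotype <- c("protein_coding", "pseudogene", "protein_coding")
  igraph::V(g)$is_ncrna <- c(FALSE, TRUE, FALSE)
  igraph::V(g)$log2_fc <- c(1.2, NA, -0.5)
  igraph::V(g)$isolated <- FALSE
  dir <- withr::local_tempdir()
  gml <- write_network_graphml(g, file.path(dir, "net.graphml"))
  back <- read_network_graphml(gml)
  expect_equal(sort(igraph::V(back)$name), sort(igraph::V(g)$name))
  expect_equal(sort(igraph::E(back)$mi), sort(igraph::E(g)$mi))
  tsv <- write_edge_list_tsv(g, file.path(dir, "net.tsv"))
  back2 <- read_edge_list_tsv(tsv)
  expect_equal(igraph::ecount(back2), 2)
  expect_equal(sort(igraph::E(back2)$distance), sort(igraph::E(g)$distance))
})
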