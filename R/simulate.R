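#' Simulation configuration
#'
#' Defines the synthetic cohort the generator emulates: two sample groups
#' (normal/tumor), subtype-structured tumor samples, implanted differentially
#' expressed gene blocks (biclusters), a minority of non-coding biotypes
#' co-expressed with specific modules, and planted "broker" ncRNAs whose
#' profiles load on the latent factors of two distinct modules.  Defaults
#' mirror a cohort of 106 normal and 124 tumor RNA-Seq samples with four
#' molecular subtypes and three implanted 20-gene x 10-sample biclusters.
#'
#' On the log2 scale every gene is Gaussian background noise
#' (mean \code{baseline_log2}, sd \code{noise_sd}); linear values are
#' \code{2^log2}, i.e. log-normal FPKM-like marginals.  Differentially
#' expressed genes receive a tumor-wide mean shift of
#' \code{effect_size * noise_sd}; bicluster member genes additionally
#' receive the same shift restricted to their (gene, sample) block, and
#' share a per-module latent factor with loading \code{module_loading} that
#' creates the co-expression structure the network stage detects.  Broker
#' ncRNAs load on the factors of two distinct modules
#' (\code{broker_loading} overall), which makes them topological bridges.
#'
#' @param n_genes number of protein-coding genes (includes block genes).
#' @param n_ncrna number of non-coding genes.
#' @param n_normal,n_tumor sample-group sizes.
#' @param subtype_proportions named fractions summing to 1; tumor subtype
#'   labels are drawn i.i.d. from these.
#' @param n_biclusters number of implanted blocks.
#' @param bicluster_gene_sizes,bicluster_sample_sizes integer vectors of
#'   length \code{n_biclusters}.
#' @param effect_size mean shift in units of \code{noise_sd} (log2 scale).
#' @param noise_sd background standard deviation on the log2 scale.
#' @param n_brokers number of planted broker ncRNAs (requires
#'   \code{n_biclusters >= 2} when positive).
#' @param n_module_ncrna non-broker ncRNAs co-expressed with single modules.
#' @param n_free_de_ncrna ncRNAs differentially expressed but independent of
#'   every module (end up isolated in the network).
#' @param n_de_extra additional DE protein-coding genes outside the blocks
#'   (half up-, half down-regulated).
#' @param contamination fraction of each block's samples drawn from subtypes
#'   other than its dominant one.
#' @param module_loading,broker_loading latent-factor loadings in [0, 1].
#' @param baseline_log2 grand mean of gene baselines on the log2 scale.
#' @param baseline_sd spread of per-gene baseline levels (log2 scale);
#'   real transcriptomes span orders of magnitude, and a realistic spread
#'   also keeps rank-based normalisation well behaved.
#' @param seed integer master seed.
#' @return a validated list of class \code{ncbroker_sim_config}.
#' @export
sim_config <- function(n_genes = 500, n_ncrna = 50,
                       n_normal = 106, n_tumor = 124,
                       subtype_proportions = c(luminal_A = 0.40, luminal_B = 0.20,
                                               normal_like = 0.15, basal = 0.25),
                       n_biclusters = 3,
                       bicluster_gene_sizes = rep(20L, n_biclusters),
                       bicluster_sample_sizes = rep(10L, n_biclusters),
                       effect_size = 3, noise_sd = 1,
                       n_brokers = 2, n_module_ncrna = 6, n_free_de_ncrna = 10,
                       n_de_extra = 60, contamination = 0.1,
                       module_loading = 0.8, broker_loading = 0.9,
                       baseline_log2 = 5, baseline_sd = 2, seed = 1) {
  # YAML configs deliver vectors as lists; accept both
  subtype_proportions <- unlist(subtype_proportions)
  bicluster_gene_sizes <- unlist(bicluster_gene_sizes)
  bicluster_sample_sizes <- unlist(bicluster_sample_sizes)
  cfg <- list(n_genes = n_genes, n_ncrna = n_ncrna, n_normal = n_normal,
              n_tumor = n_tumor, subtype_proportions = subtype_proportions,
              n_biclusters = n_biclusters,
              bicluster_gene_sizes = as.integer(bicluster_gene_sizes),
              bicluster_sample_sizes = as.integer(bicluster_sample_sizes),
              effect_size = effect_size, noise_sd = noise_sd,
              n_brokers = n_brokers, n_module_ncrna = n_module_ncrna,
              n_free_de_ncrna = n_free_de_ncrna, n_de_extra = n_de_extra,
              contamination = contamination, module_loading = module_loading,
              broker_loading = broker_loading, baseline_log2 = baseline_log2,
              baseline_sd = baseline_sd, seed = as.integer(seed))
  counts <- c(n_genes, n_ncrna, n_normal, n_tumor, n_biclusters, n_brokers,
              n_module_ncrna, n_free_de_ncrna, n_de_extra)
  if (any(counts < 0)) stop("configuration error: counts must be >= 0")
  if (abs(sum(subtype_proportions) - 1) > 1e-9) {
    stop("configuration error: subtype_proportions must sum to 1")
  }
  if (length(cfg$bicluster_gene_sizes) != n_biclusters ||
      length(cfg$bicluster_sample_sizes) != n_biclusters) {
    stop("configuration error: bicluster size vectors must have length n_biclusters")
  }
  if (n_biclusters > 0 && any(cfg$bicluster_gene_sizes < 1)) {
    stop("configuration error: every bicluster_gene_size must be >= 1")
  }
  if (n_brokers > n_ncrna) stop("configuration error: n_brokers must be <= n_ncrna")
  if (n_brokers > 0 && n_biclusters < 2) {
    stop("configuration error: brokers need at least 2 biclusters to bridge")
  }
  if (n_brokers + n_module_ncrna + n_free_de_ncrna > n_ncrna) {
    stop("configuration error: ncRNA role counts exceed n_ncrna")
  }
  if (sum(cfg$bicluster_gene_sizes) > n_genes) {
    stop("configuration error: block genes exceed n_genes")
  }
  if (noise_sd <= 0) stop("configuration error: noise_sd must be positive")
  if (module_loading < 0 || module_loading > 1 ||
      broker_loading < 0 || broker_loading > 1) {
    stop("configuration error: loadings must lie in [0, 1]")
  }
  structure(cfg, class = "ncbroker_sim_config")
}

# Relative biotype frequencies for the simulated non-coding genes; roughly
# the pseudogene-dominated mix seen in DE ncRNA catalogues.
NC_BIOTYPE_FREQ <- c(pseudogene = 0.64, antisense = 0.16, lincRNA = 0.11,
                     processed_transcript = 0.04, "repeat" = 0.05)

#' Simulate an expression cohort with known ground truth
#'
#' Generates a linear-scale (FPKM-like) expression matrix plus metadata from
#' a \code{\link{sim_config}}, together with the ground truth needed to
#' benchmark every downstream stage: which genes are differentially
#' expressed, the implanted bicluster memberships with their dominant
#' subtype, the planted broker ncRNAs, and the gene -> module map.
#' Byte-identical output for identical seeds.
#'
#' @param config a \code{ncbroker_sim_config}.
#' @return list with elements \code{expr} (an \code{\link{expression_matrix}})
#'   and \code{truth} (list: de_gene_ids, bicluster_memberships, broker_ids,
#'   module_assignments).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "ncbroker_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_samp <- cfg$n_normal + cfg$n_tumor
    sample_ids <- c(sprintf("N%03d", seq_len(cfg$n_normal)),
                    sprintf("T%03d", seq_len(cfg$n_tumor)))
    group <- stats::setNames(rep(c("normal", "tumor"), c(cfg$n_normal, cfg$n_tumor)),
                             sample_ids)
    tumor_ids <- sample_ids[group == "tumor"]
    subtypes <- names(cfg$subtype_proportions)
    subtype <- stats::setNames(
      sample(subtypes, cfg$n_tumor, replace = TRUE, prob = cfg$subtype_proportions),
      tumor_ids)

    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    nc_ids <- if (cfg$n_ncrna > 0) sprintf("NC%03d", seq_len(cfg$n_ncrna)) else character()
    all_ids <- c(gene_ids, nc_ids)
    biotype <- c(stats::setNames(rep("protein_coding", cfg$n_genes), gene_ids),
                 stats::setNames(sample(names(NC_BIOTYPE_FREQ), cfg$n_ncrna,
                                        replace = TRUE, prob = NC_BIOTYPE_FREQ),
                                 nc_ids))

    shift <- cfg$effect_size * cfg$noise_sd
    lam <- cfg$module_loading
    is_tumor <- as.numeric(group == "tumor")

    # per-gene baseline levels plus background log2 noise
    mu <- stats::setNames(
      stats::rnorm(length(all_ids), cfg$baseline_log2, cfg$baseline_sd), all_ids)
    L <- mu + matrix(stats::rnorm(length(all_ids) * n_samp, 0, cfg$noise_sd),
                     nrow = length(all_ids), dimnames = list(all_ids, sample_ids))

    # module latent factors, one per implanted bicluster, over all samples
    factors <- if (cfg$n_biclusters > 0) {
      matrix(stats::rnorm(cfg$n_biclusters * n_samp), nrow = cfg$n_biclusters,
             dimnames = list(NULL, sample_ids))
    } else {
      matrix(0, 0, n_samp)
    }

    # disjoint block gene sets
    pool <- sample(gene_ids)
    block_genes <- list()
    off <- 0L
    memberships <- list()
    module_assign <- character(0)
    de_ids <- character(0)
    for (m in seq_len(cfg$n_biclusters)) {
      ng <- cfg$bicluster_gene_sizes[m]
      gset <- pool[(off + 1L):(off + ng)]
      off <- off + ng
      block_genes[[m]] <- gset
      dom <- subtypes[((m - 1L) %% length(subtypes)) + 1L]
      ns <- cfg$bicluster_sample_sizes[m]
      n_dom <- max(1L, ceiling((1 - cfg$contamination) * ns))
      n_dom <- min(n_dom, ns)
      dom_pool <- tumor_ids[subtype[tumor_ids] == dom]
      oth_pool <- setdiff(tumor_ids, dom_pool)
      n_oth <- min(ns - n_dom, length(oth_pool))   # contamination is "up to"
      n_dom <- ns - n_oth
      if (length(dom_pool) < n_dom) {
        stop("configuration error: not enough tumor samples of subtype '", dom,
             "' for bicluster ", m)
      }
      sset <- c(sample(dom_pool, n_dom), sample(oth_pool, n_oth))
      # The block lives in the module factor: block samples carry a factor
      # offset of effect_size / loading, so every gene loading on the factor
      # is raised by effect_size * noise_sd inside the block, and the
      # bicluster is the factor's high tail rather than an independent
      # per-cell shift.  On top of that, a tumor-wide DE shift makes the
      # block genes differentially expressed.
      if (lam > 0) {
        factors[m, sset] <- factors[m, sset] + cfg$effect_size / lam
        L[gset, ] <- mu[gset] + cfg$noise_sd *
          (lam * matrix(factors[m, ], ng, n_samp, byrow = TRUE) +
             sqrt(1 - lam^2) *
             matrix(stats::rnorm(ng * n_samp), ng, n_samp))
      } else {
        L[gset, sset] <- L[gset, sset] + shift
      }
      L[gset, ] <- L[gset, ] + matrix(shift * is_tumor, ng, n_samp, byrow = TRUE)
      memberships[[m]] <- list(genes = sort(gset), samples = sort(sset),
                               dominant_subtype = dom)
      module_assign[gset] <- paste0("M", m)
      if (shift > 0) de_ids <- c(de_ids, gset)
    }

    # extra DE protein-coding genes outside the blocks
    rest <- if (off < length(pool)) pool[(off + 1L):length(pool)] else character()
    n_extra <- min(cfg$n_de_extra, length(rest))
    if (n_extra > 0 && shift > 0) {
      extra <- rest[seq_len(n_extra)]
      sgn <- rep(c(1, -1), length.out = n_extra)
      L[extra, ] <- L[extra, ] +
        outer(sgn * shift, is_tumor)
      de_ids <- c(de_ids, extra)
    }

    # ncRNA roles: brokers bridge consecutive module pairs; module-linked
    # ncRNAs load on a single factor; free DE ncRNAs shift without structure
    broker_ids <- character(0)
    if (cfg$n_ncrna > 0) {
      nc_pool <- sample(nc_ids)
      take <- function(n) {
        if (n == 0L) return(character())
        out <- nc_pool[seq_len(n)]
        nc_pool <<- nc_pool[-seq_len(n)]
        out
      }
      if (cfg$n_brokers > 0) {
        broker_ids <- sort(take(cfg$n_brokers))
        lb <- cfg$broker_loading
        for (i in seq_along(broker_ids)) {
          a <- ((i - 1L) %% cfg$n_biclusters) + 1L
          b <- (i %% cfg$n_biclusters) + 1L
          f <- (factors[a, ] + factors[b, ]) / sqrt(2)
          L[broker_ids[i], ] <- mu[broker_ids[i]] + cfg$noise_sd *
            (lb * f + sqrt(1 - lb^2) * stats::rnorm(n_samp)) +
            shift * is_tumor
        }
        if (shift > 0) de_ids <- c(de_ids, broker_ids)
      }
      if (cfg$n_module_ncrna > 0 && cfg$n_biclusters > 0) {
        mods <- take(cfg$n_module_ncrna)
        for (i in seq_along(mods)) {
          m <- ((i - 1L) %% cfg$n_biclusters) + 1L
          L[mods[i], ] <- mu[mods[i]] + cfg$noise_sd *
            (lam * factors[m, ] + sqrt(1 - lam^2) * stats::rnorm(n_samp)) +
            shift * is_tumor
          module_assign[mods[i]] <- paste0("M", m)
        }
        if (shift > 0) de_ids <- c(de_ids, mods)
      }
      if (cfg$n_free_de_ncrna > 0 && shift > 0) {
        free <- take(cfg$n_free_de_ncrna)
        L[free, ] <- L[free, ] + outer(rep(shift, length(free)), is_tumor)
        de_ids <- c(de_ids, free)
      }
    }

    expr <- expression_matrix(2^L, group, subtype, biotype, scale = "linear")
    truth <- list(
      de_gene_ids = sort(unique(de_ids)),
      bicluster_memberships = memberships,
      broker_ids = broker_ids,
      module_assignments = module_assign
    )
    list(expr = expr, truth = truth)
  })
}

#' Benchmark graph with planted bridge (broker) nodes
#'
#' Builds disjoint cliques joined only through designated bridge nodes and
#' returns the bridge labels as ground-truth brokers.  Bridge i connects
#' cliques i and i + 1 (extra bridges connect random clique pairs), and is
#' attached to \code{max(2, floor(clique_size / 2))} members of each of its
#' two cliques: multi-edge attachment keeps the bridge's neighbourhood split
#' in two well-connected halves, which is what gives bridge nodes the
#' highest brokerage in the graph.
#'
#' @param n_cliques number of cliques (>= 1).
#' @param clique_size nodes per clique (>= 2).
#' @param n_bridges number of bridge nodes.
#' @param seed integer seed for the random attachments.
#' @param connected require the result to be connected (then
#'   \code{n_bridges >= n_cliques - 1} must hold).
#' @return an undirected \code{igraph} with logical vertex attribute
#'   \code{is_bridge}; the bridge names are also in the graph attribute
#'   \code{broker_ids}.
#' @export
generate_broker_graph <- function(n_cliques, clique_size, n_bridges, seed = 1,
                                  connected = TRUE) {
  if (n_cliques < 1 || clique_size < 2) {
    stop("configuration error: need n_cliques >= 1 and clique_size >= 2")
  }
  if (connected && n_cliques > 1 && n_bridges < n_cliques - 1) {
    stop("configuration error: connectivity needs n_bridges >= n_cliques - 1")
  }
  with_seed(seed, {
    clique_nodes <- lapply(seq_len(n_cliques), function(i) {
      sprintf("c%d_%d", i, seq_len(clique_size))
    })
    edges <- character(0)
    for (nodes in clique_nodes) {
      pr <- utils::combn(nodes, 2)
      edges <- c(edges, as.vector(pr))
    }
    bridge_ids <- if (n_bridges > 0) sprintf("b%d", seq_len(n_bridges)) else character()
    m <- min(max(2L, floor(clique_size / 2)), clique_size)
    for (i in seq_len(n_bridges)) {
      if (i <= n_cliques - 1) {
        pair <- c(i, i + 1L)
      } else {
        pair <- sample(n_cliques, 2L)
      }
      for (cl in pair) {
        anchors <- sample(clique_nodes[[cl]], m)
        edges <- c(edges, as.vector(rbind(bridge_ids[i], anchors)))
      }
    }
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, length(unlist(clique_nodes)) + length(bridge_ids),
                              name = c(unlist(clique_nodes), bridge_ids))
    g <- igraph::add_edges(g, edges)
    igraph::V(g)$is_bridge <- igraph::V(g)$name %in% bridge_ids
    g <- igraph::set_graph_attr(g, "broker_ids", bridge_ids)
    g
  })
}

#' Write a simulated cohort to disk
#'
#' Writes the matrix/metadata/biotype TSVs (via
#' \code{\link{write_expression_tsv}}) plus the ground truth as JSON.
#'
#' @param sim result of \code{\link{simulate_expression}}.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  paths <- write_expression_tsv(sim$expr, dir)
  tf <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sim$truth, tf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, truth = tf))
}
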