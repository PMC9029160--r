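# Mutual-information template networks: MI estimation, permutation
# significance, bootstrap edge persistence, and network assembly with the
# distance d = 1 - MI stored on every edge.

# Equal-frequency discretisation into n_bins bins (rank-based, deterministic).
discretize_ef <- function(v, n_bins) {
  n <- length(v)
  pmin(ceiling(rank(v, ties.method = "first") * n_bins / n), n_bins)
}

# Plug-in MI (bits) of two integer bin vectors, normalised by min entropy.
mi_from_bins <- function(ix, iy, n_bins) {
  joint <- tabulate((ix - 1L) * n_bins + iy, nbins = n_bins * n_bins)
  n <- length(ix)
  p <- joint[joint > 0] / n
  px <- tabulate(ix, n_bins) / n
  py <- tabulate(iy, n_bins) / n
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  if (hx == 0 || hy == 0) return(0)
  # MI = H(X) + H(Y) - H(X,Y)
  hxy <- -sum(p * log2(p))
  mi <- hx + hy - hxy
  max(0, min(1, mi / min(hx, hy)))
}

expr_submatrix <- function(x, genes = NULL, samples = NULL) {
  E <- if (inherits(x, "ncb_expr")) x$values else as.matrix(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(E))
    if (length(missing)) stop("unknown gene id(s): ", paste(missing, collapse = ", "))
    E <- E[genes, , drop = FALSE]
  }
  if (!is.null(samples)) E <- E[, samples, drop = FALSE]
  E
}

# Tertile (low/medium/high) discretisation by default.  At cohort sizes of
# order 100 samples, finer grids inflate the plug-in MI of independent pairs
# (bias and tail both grow with the cell count) faster than they add
# sensitivity to monotone dependence, and the null tail is what limits
# network-scale edge significance.  Finer grids remain available via n_bins.
default_bins <- function(n_samples) 3L

#' Pairwise normalised mutual information
#'
#' Plug-in MI from equal-frequency discretisation into \code{n_bins} bins,
#' normalised to [0, 1] by the smaller marginal entropy, so the distance
#' d = 1 - MI also lies in [0, 1].  The diagonal is 1 for non-constant
#' genes; a constant gene has zero entropy and its normalised MI is defined
#' as 0 against every partner.
#'
#' @param x \code{ncb_expr} (log2 scale) or numeric matrix, genes as rows.
#' @param genes gene ids (rows) to include; default all.
#' @param n_bins number of bins; default \code{ceiling(n_samples^(1/3))}.
#' @param samples optional sample restriction.
#' @return symmetric matrix of normalised MI values.
#' @export
pairwise_mi <- function(x, genes = NULL, n_bins = NULL, samples = NULL) {
  E <- expr_submatrix(x, genes, samples)
  n <- ncol(E)
  if (n < 8L) stop("need at least 8 samples for MI estimation")
  n_bins <- n_bins %||% default_bins(n)
  ng <- nrow(E)
  const <- row_sds(E) == 0
  if (any(const)) {
    message("constant gene(s) assigned zero MI: ",
            paste(rownames(E)[const], collapse = ", "))
  }
  bins <- t(apply(E, 1L, discretize_ef, n_bins = n_bins))
  M <- matrix(0, ng, ng, dimnames = list(rownames(E), rownames(E)))
  for (i in seq_len(ng)) {
    if (const[i]) next
    M[i, i] <- 1
    if (i == ng) break
    for (j in (i + 1L):ng) {
      if (const[j]) next
      M[i, j] <- M[j, i] <- mi_from_bins(bins[i, ], bins[j, ], n_bins)
    }
  }
  M
}

#' Pairwise absolute Spearman correlation
#'
#' The correlation counterpart used only for the MI-vs-COR comparison
#' report; constant genes get 0.
#'
#' @inheritParams pairwise_mi
#' @return symmetric matrix of |Spearman rho|.
#' @export
pairwise_correlation <- function(x, genes = NULL, samples = NULL) {
  E <- expr_submatrix(x, genes, samples)
  if (ncol(E) < 8L) stop("need at least 8 samples")
  const <- row_sds(E) == 0
  M <- abs(stats::cor(t(E), method = "spearman"))
  M[const, ] <- 0
  M[, const] <- 0
  diag(M)[const] <- 0
  M
}

#' Permutation null for one gene pair's MI
#'
#' Recomputes the MI after independently permuting one gene's sample order
#' \code{n_perm} times; the p-value carries the add-one correction
#' \code{(1 + #\{null >= observed\}) / (1 + n_perm)}, so the smallest
#' achievable p is \code{1/(n_perm + 1)} and p can never be 0.
#'
#' @param x \code{ncb_expr} or matrix.
#' @param pair character vector of two gene ids.
#' @param n_perm number of permutations (>= 20; default 1000).
#' @param seed RNG seed.
#' @param n_bins bins (default \code{ceiling(n_samples^(1/3))}).
#' @param samples optional sample restriction.
#' @return list with \code{pair}, \code{observed}, \code{null_samples},
#'   \code{null_p}.
#' @export
permutation_null <- function(x, pair, n_perm = 1000, seed = 1, n_bins = NULL,
                             samples = NULL) {
  if (n_perm < 20) stop("configuration error: n_perm must be >= 20")
  E <- expr_submatrix(x, pair, samples)
  n <- ncol(E)
  n_bins <- n_bins %||% default_bins(n)
  ix <- discretize_ef(E[1L, ], n_bins)
  iy <- discretize_ef(E[2L, ], n_bins)
  obs <- if (row_sds(E)[1L] == 0 || row_sds(E)[2L] == 0) 0 else
    mi_from_bins(ix, iy, n_bins)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mi_from_bins(ix, iy[sample.int(n)], n_bins)
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  if (obs == 0) p <- 1
  list(pair = pair, observed = obs, null_samples = null, null_p = p)
}

# Shared permutation null: with equal-frequency binning of continuous data
# every gene has the same marginal bin counts, so one permuted-pair null
# serves all pairs with those marginals.  Returns sorted null draws.
shared_mi_null <- function(n, n_bins, n_perm, seed) {
  ix <- pmin(ceiling(seq_len(n) * n_bins / n), n_bins)
  iy <- ix
  with_seed(seed, {
    sort(vapply(seq_len(n_perm), function(i) {
      mi_from_bins(ix[sample.int(n)], iy[sample.int(n)], n_bins)
    }, numeric(1)))
  })
}

#' Bootstrap persistence of candidate edges
#'
#' For each of \code{n_randomizations} bootstrap resamplings of the samples,
#' the MI of every candidate edge is recomputed and the edge counts as
#' re-appearing when its MI reaches \code{mi_threshold}.  Persistence is the
#' fraction of resamplings in which the edge re-appears ("rewiring
#' strength").
#'
#' @param x \code{ncb_expr} or matrix.
#' @param candidate_edges two-column character matrix of gene pairs.
#' @param mi_threshold MI level an edge must reach inside a resampling.
#' @param n_randomizations bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @param n_bins bins (default \code{ceiling(n_samples^(1/3))}).
#' @param samples optional sample restriction.
#' @return numeric vector of persistence values in [0, 1], one per edge.
#' @export
rewiring_persistence <- function(x, candidate_edges, mi_threshold,
                                 n_randomizations = 100, seed = 1,
                                 n_bins = NULL, samples = NULL) {
  E <- expr_submatrix(x, NULL, samples)
  n <- ncol(E)
  if (n < 8L) stop("need at least 8 samples")
  candidate_edges <- as.matrix(candidate_edges)
  if (nrow(candidate_edges) == 0L) return(numeric(0))
  n_bins <- n_bins %||% default_bins(n)
  nodes <- unique(as.vector(candidate_edges))
  E <- E[nodes, , drop = FALSE]
  i1 <- match(candidate_edges[, 1L], nodes)
  i2 <- match(candidate_edges[, 2L], nodes)
  hits <- numeric(nrow(candidate_edges))
  with_seed(seed, {
    for (b in seq_len(n_randomizations)) {
      idx <- sample.int(n, n, replace = TRUE)
      Eb <- E[, idx, drop = FALSE]
      bins <- t(apply(Eb, 1L, discretize_ef, n_bins = n_bins))
      mis <- vapply(seq_along(i1), function(k) {
        mi_from_bins(bins[i1[k], ], bins[i2[k], ], n_bins)
      }, numeric(1))
      hits <- hits + (mis >= mi_threshold)
    }
  })
  stats::setNames(hits / n_randomizations,
                  paste(candidate_edges[, 1L], candidate_edges[, 2L], sep = "|"))
}

#' Build the template co-expression network
#'
#' Assembles the undirected template network over the signature-bicluster
#' genes and the differentially expressed ncRNAs: pairwise normalised MI is
#' computed on the chosen samples, each pair is tested against a permutation
#' null, and the significant pairs are additionally required to re-appear in
#' at least \code{min_persistence} of the bootstrap network rebuilds.  Kept
#' edges carry \code{mi}, \code{distance} = 1 - mi, \code{null_p} and
#' \code{persistence}; nodes carry \code{biotype}, \code{log2_fc} and
#' \code{is_ncrna}, and nodes left without any edge are retained with
#' \code{isolated = TRUE}.
#'
#' The permutation null is pooled across pairs by default
#' (\code{null_mode = "pooled"}): under equal-frequency binning of
#' continuous data every gene shares the same marginal bin counts, so the
#' permuted-pair MI distribution is common to all pairs and one null serves
#' the whole matrix.  \code{"per_edge"} recomputes it pair by pair.
#'
#' Significance is controlled family-wise by default
#' (\code{correction = "family"}): \code{alpha} is divided by the number of
#' tested pairs (Bonferroni) and the pooled null is enlarged so the
#' corrected quantile is resolvable.  Testing thousands of pairs at a raw
#' per-edge level would otherwise guarantee on the order of
#' \code{alpha * n_pairs} false edges, which bootstrap persistence cannot
#' remove (a chance edge persists because resampling preserves the lucky
#' sample pairing).  \code{correction = "none"} applies \code{alpha} per
#' edge, which is the right mode for calibration studies of the test
#' itself.  The persistence MI threshold is the corresponding null
#' quantile.
#'
#' @param x \code{ncb_expr} on the log2 scale.
#' @param genes character vector of gene ids (non-empty).
#' @param ncrna character vector of ncRNA ids (may be empty).
#' @param alpha significance level for the permutation test (default 0.05).
#' @param min_persistence minimum bootstrap persistence (default 0.8).
#' @param n_perm permutation draws (default 1000).
#' @param n_boot bootstrap rebuilds (default 100).
#' @param n_bins bins (default \code{ceiling(n_samples^(1/3))}).
#' @param samples \code{"tumor"} (default: template maps condition on the
#'   tumor group), \code{"all"}, or an explicit id vector.
#' @param seed RNG seed.
#' @param metric \code{"mi"} (default) or \code{"cor"} for the comparison
#'   path (|Spearman| with the same permutation/bootstrap machinery;
#'   \code{distance} is then 1 - |rho|).
#' @param de optional DE table (from \code{\link{differential_expression}})
#'   supplying \code{log2_fc} node attributes.
#' @param null_mode \code{"pooled"} or \code{"per_edge"}.
#' @param correction \code{"family"} (Bonferroni over the tested pairs,
#'   default) or \code{"none"} (raw per-edge alpha).
#' @return an \code{igraph} of class \code{ncb_network}/\code{igraph} with
#'   graph attributes \code{metric}, \code{alpha}, \code{min_persistence},
#'   \code{mi_threshold}.
#' @export
build_template_network <- function(x, genes, ncrna = character(),
                                   alpha = 0.05, min_persistence = 0.8,
                                   n_perm = 1000, n_boot = 100, n_bins = NULL,
                                   samples = "tumor", seed = 1,
                                   metric = c("mi", "cor"), de = NULL,
                                   null_mode = c("pooled", "per_edge"),
                                   correction = c("family", "none")) {
  metric <- match.arg(metric)
  null_mode <- match.arg(null_mode)
  correction <- match.arg(correction)
  if (length(genes) == 0L) stop("empty gene list")
  if (inherits(x, "ncb_expr") && is.character(samples) && length(samples) == 1L &&
      samples %in% c("tumor", "all")) {
    samples <- if (samples == "tumor") names(x$group)[x$group == "tumor"] else NULL
  }
  nodes <- unique(c(genes, ncrna))
  E <- expr_submatrix(x, nodes, samples)
  n <- ncol(E)
  n_bins <- n_bins %||% default_bins(n)

  M <- if (metric == "mi") {
    pairwise_mi(E, n_bins = n_bins)
  } else {
    pairwise_correlation(E)
  }
  pairs <- which(upper.tri(M), arr.ind = TRUE)
  obs <- M[pairs]
  n_pairs <- nrow(pairs)
  alpha_eff <- if (correction == "family") alpha / max(1L, n_pairs) else alpha
  # enough pooled draws to resolve the corrected tail quantile
  n_null <- if (correction == "family" && alpha_eff > 0) {
    max(n_perm, min(5e5L, as.integer(ceiling(10 / alpha_eff))))
  } else {
    n_perm
  }

  if (null_mode == "pooled" || metric == "cor") {
    null <- if (metric == "mi") {
      shared_mi_null(n, n_bins, n_null, stage_seed(seed, "null"))
    } else {
      with_seed(stage_seed(seed, "null"), {
        sort(vapply(seq_len(n_null), function(i) {
          abs(stats::cor(seq_len(n), sample.int(n), method = "spearman"))
        }, numeric(1)))
      })
    }
    # p = (1 + #{null >= obs}) / (1 + n_null) via the sorted pooled null
    geq <- n_null - findInterval(obs - 1e-15, null)
    null_p <- (1 + geq) / (1 + n_null)
    mi_threshold <- stats::quantile(null, 1 - alpha_eff, names = FALSE, type = 1)
  } else {
    null_p <- numeric(length(obs))
    for (k in seq_len(n_pairs)) {
      pn <- permutation_null(E, rownames(M)[c(pairs[k, 1L], pairs[k, 2L])],
                             n_perm = n_perm,
                             seed = stage_seed(seed, paste0("null", k)),
                             n_bins = n_bins)
      null_p[k] <- pn$null_p
    }
    null <- shared_mi_null(n, n_bins, n_null, stage_seed(seed, "null"))
    mi_threshold <- stats::quantile(null, 1 - alpha_eff, names = FALSE, type = 1)
  }
  null_p[obs == 0] <- 1

  cand <- which(null_p <= alpha_eff & obs >= mi_threshold)
  edge_mat <- cbind(rownames(M)[pairs[cand, 1L]], rownames(M)[pairs[cand, 2L]])
  persistence <- if (length(cand)) {
    if (metric == "mi") {
      rewiring_persistence(E, edge_mat, mi_threshold,
                           n_randomizations = n_boot,
                           seed = stage_seed(seed, "boot"), n_bins = n_bins)
    } else {
      cor_persistence(E, edge_mat, mi_threshold, n_boot,
                      stage_seed(seed, "boot"))
    }
  } else {
    numeric(0)
  }
  keep <- which(persistence >= min_persistence)

  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(keep)) {
    g <- igraph::add_edges(g, as.vector(t(edge_mat[keep, , drop = FALSE])))
    igraph::E(g)$mi <- unname(obs[cand][keep])
    igraph::E(g)$distance <- 1 - unname(obs[cand][keep])
    igraph::E(g)$null_p <- unname(null_p[cand][keep])
    igraph::E(g)$persistence <- unname(persistence[keep])
  } else {
    warning("no edge survived significance and persistence filtering")
  }
  bt <- if (inherits(x, "ncb_expr")) x$biotype[nodes] else
    stats::setNames(rep("unannotated", length(nodes)), nodes)
  igraph::V(g)$biotype <- unname(bt)
  igraph::V(g)$is_ncrna <- nodes %in% ncrna
  lfc <- rep(NA_real_, length(nodes))
  if (!is.null(de)) {
    idx <- match(nodes, de$gene_id)
    lfc <- de$log2_fc[idx]
  }
  igraph::V(g)$log2_fc <- lfc
  igraph::V(g)$isolated <- igraph::degree(g) == 0
  g <- igraph::set_graph_attr(g, "metric", toupper(metric))
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  g <- igraph::set_graph_attr(g, "min_persistence", min_persistence)
  g <- igraph::set_graph_attr(g, "mi_threshold", unname(mi_threshold))
  class(g) <- c("ncb_network", class(g))
  g
}

# Bootstrap persistence for the correlation path.
cor_persistence <- function(E, edge_mat, thr, n_boot, seed) {
  n <- ncol(E)
  nodes <- unique(as.vector(edge_mat))
  Es <- E[nodes, , drop = FALSE]
  i1 <- match(edge_mat[, 1L], nodes)
  i2 <- match(edge_mat[, 2L], nodes)
  hits <- numeric(nrow(edge_mat))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      Cb <- abs(stats::cor(t(Es[, idx, drop = FALSE]), method = "spearman"))
      hits <- hits + (Cb[cbind(i1, i2)] >= thr)
    }
  })
  stats::setNames(hits / n_boot, paste(edge_mat[, 1L], edge_mat[, 2L], sep = "|"))
}

#' Degree-preserving edge-swap null graph
#'
#' Rewires a graph by repeated double-edge swaps, preserving every node's
#' degree; used for topology-level comparisons (the data-level null is the
#' bootstrap in \code{\link{rewiring_persistence}}).
#'
#' @param g igraph.
#' @param n_swaps number of attempted swaps (default 10 x edge count).
#' @param seed RNG seed.
#' @return the rewired igraph.
#' @export
edge_swap_null <- function(g, n_swaps = 10 * igraph::ecount(g), seed = 1) {
  with_seed(seed, {
    igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
  })
}

#' Write / read a template network
#'
#' GraphML keeps all node and edge attributes; the flat edge list TSV has
#' columns source, target, mi, distance, null_p, persistence.
#'
#' @param g the network.
#' @param path output file.
#' @export
write_network_graphml <- function(g, path) {
  g2 <- g
  class(g2) <- "igraph"
  # GraphML cannot hold NA reals; encode missing log2_fc as NaN
  lfc <- igraph::V(g2)$log2_fc
  if (!is.null(lfc)) igraph::V(g2)$log2_fc <- ifelse(is.na(lfc), NaN, lfc)
  igraph::write_graph(g2, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  class(g) <- c("ncb_network", class(g))
  g
}

#' @rdname write_network_graphml
#' @export
write_edge_list_tsv <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(source = el[, 1L], target = el[, 2L],
                   mi = igraph::E(g)$mi, distance = igraph::E(g)$distance,
                   null_p = igraph::E(g)$null_p,
                   persistence = igraph::E(g)$persistence,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_edge_list_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::E(g)$distance <- df$distance
  class(g) <- c("ncb_network", class(g))
  g
}
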