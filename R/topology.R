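# Node topology battery: clustering coefficient, Burt effective size, local
# efficiency, brokerage B = k - (k - 1)E, articulation points and bridges,
# disruption profiles under targeted removal.

check_node <- function(g, node) {
  if (!node %in% igraph::V(g)$name) stop("node not in graph: ", node)
}

graph_with_names <- function(g) {
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

#' Local clustering coefficient
#'
#' 2 t / (k (k - 1)) where t is the number of edges among the node's
#' neighbours; 0 for degree below 2.
#'
#' @param g undirected simple igraph.
#' @param node node name (default: all nodes).
#' @return named numeric vector in [0, 1].
#' @export
clustering_coefficient <- function(g, node = NULL) {
  g <- graph_with_names(g)
  vids <- if (is.null(node)) igraph::V(g) else {
    check_node(g, node); node
  }
  cc <- igraph::transitivity(g, type = "local", vids = vids, weights = NA,
                             isolates = "zero")
  cc[is.na(cc)] <- 0
  stats::setNames(cc, if (is.null(node)) igraph::V(g)$name else node)
}

#' Burt effective size (unweighted)
#'
#' S = k - 2 t / k, the non-redundant part of the neighbourhood: each edge
#' among the node's neighbours makes one contact redundant.  Isolated nodes
#' have S = 0 by convention.
#'
#' @inheritParams clustering_coefficient
#' @return named numeric vector.
#' @export
effective_size <- function(g, node = NULL) {
  g <- graph_with_names(g)
  names <- if (is.null(node)) igraph::V(g)$name else {
    check_node(g, node); node
  }
  k <- igraph::degree(g, v = names)
  # t_i via local transitivity: t = C * k (k-1) / 2
  cc <- clustering_coefficient(g)[names]
  t_i <- cc * k * (k - 1) / 2
  s <- ifelse(k > 0, k - 2 * t_i / k, 0)
  stats::setNames(unname(s), names)
}

#' Local efficiency
#'
#' Builds the subgraph induced by the node's neighbours -- the node itself
#' excluded, so paths between neighbours may not route through it -- and
#' averages the inverse shortest-path lengths over unordered neighbour
#' pairs, with 1/Inf = 0 for disconnected pairs.  E = 0 for degree below 2.
#' The exclusion of the focal node is what makes the derived brokerage
#' detect brokers: a broker's neighbours fall apart without it.
#'
#' @inheritParams clustering_coefficient
#' @param weighted use the edge attribute \code{distance} (= 1 - MI) as path
#'   length instead of hop counts; exploratory, off by default.
#' @return named numeric vector in [0, 1] (can exceed 1 when weighted
#'   distances are shorter than hops).
#' @export
local_efficiency <- function(g, node = NULL, weighted = FALSE) {
  g <- graph_with_names(g)
  names <- if (is.null(node)) igraph::V(g)$name else {
    check_node(g, node); node
  }
  eff <- vapply(names, function(v) {
    nb <- igraph::neighbors(g, v)$name
    nb <- setdiff(unique(nb), v)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    w <- if (weighted && !is.null(igraph::E(sub)$distance)) {
      igraph::E(sub)$distance
    } else {
      NA
    }
    D <- igraph::distances(sub, weights = w)
    inv <- 1 / D[upper.tri(D)]
    inv[!is.finite(inv)] <- 0
    mean(inv)
  }, numeric(1))
  stats::setNames(unname(eff), names)
}

#' Brokerage
#'
#' B = k - (k - 1) E with E the local efficiency.  B ranges from 1 (the
#' neighbourhood stays fully connected without the node, E = 1) to k (the
#' neighbourhood shatters, E = 0), so high values flag nodes that bridge
#' otherwise-disconnected neighbours.  Conventions: B = 0 for isolated
#' nodes, B = 1 for degree 1.
#'
#' @inheritParams local_efficiency
#' @return named numeric vector.
#' @export
brokerage <- function(g, node = NULL, weighted = FALSE) {
  g <- graph_with_names(g)
  names <- if (is.null(node)) igraph::V(g)$name else {
    check_node(g, node); node
  }
  k <- igraph::degree(g, v = names)
  e <- local_efficiency(g, node = node, weighted = weighted)
  b <- ifelse(k == 0, 0, k - (k - 1) * e)
  stats::setNames(unname(b), names)
}

#' Min-max normalised brokerage
#'
#' Normalises B over all nodes of degree >= 1 to [0, 1]; isolated nodes get
#' 0, and when every B is equal the normalised value is defined as 1.
#'
#' @inheritParams local_efficiency
#' @return named numeric vector in [0, 1] over all nodes.
#' @export
normalized_brokerage <- function(g, weighted = FALSE) {
  g <- graph_with_names(g)
  b <- brokerage(g, weighted = weighted)
  k <- igraph::degree(g)
  out <- stats::setNames(rep(0, length(b)), names(b))
  act <- k >= 1
  if (!any(act)) return(out)
  rng <- range(b[act])
  out[act] <- if (diff(rng) == 0) 1 else (b[act] - rng[1L]) / diff(rng)
  out
}

#' Articulation points and bridges
#'
#' Standard cut-vertex and cut-edge detection (depth-first low-link, via
#' igraph).
#'
#' @param g undirected igraph.
#' @return list with \code{articulation} (node names) and \code{bridges}
#'   (two-column character matrix of edges).
#' @export
articulation_and_bridges <- function(g) {
  g <- graph_with_names(g)
  ap <- igraph::articulation_points(g)
  br <- igraph::bridges(g)
  bm <- igraph::as_edgelist(igraph::subgraph_from_edges(g, br, delete.vertices = FALSE))
  bm <- matrix(as.character(bm), ncol = 2)
  list(articulation = sort(igraph::V(g)$name[as.integer(ap)]),
       bridges = bm[order(bm[, 1L], bm[, 2L]), , drop = FALSE])
}

#' Per-node topology report
#'
#' One row per node: degree, clustering coefficient, effective size, local
#' efficiency, brokerage, normalised brokerage, articulation flag, plus
#' betweenness centrality for comparison (betweenness is reported but never
#' used in broker ranking).
#'
#' @param g undirected igraph.
#' @return data.frame ordered by node name.
#' @export
node_topology <- function(g) {
  g <- graph_with_names(g)
  nm <- igraph::V(g)$name
  ap <- articulation_and_bridges(g)$articulation
  df <- data.frame(
    node_id = nm,
    biotype = igraph::V(g)$biotype %||% rep(NA_character_, length(nm)),
    degree = unname(igraph::degree(g)),
    clustering = unname(clustering_coefficient(g)),
    effective_size = unname(effective_size(g)),
    local_efficiency = unname(local_efficiency(g)),
    brokerage = unname(brokerage(g)),
    normalized_brokerage = unname(normalized_brokerage(g)),
    is_articulation = nm %in% ap,
    betweenness = unname(igraph::betweenness(g, weights = NA)),
    stringsAsFactors = FALSE
  )
  df[order(df$node_id), ]
}

#' Disruption profile under targeted node removal
#'
#' Removes the target nodes cumulatively in the given order, recording the
#' number of connected components and the giant-component fraction
#' (largest component size over the ORIGINAL node count) after each step.
#' The baseline repeats this with random removal sequences degree-matched to
#' the targets within +/- 1 (the tolerance widens one step at a time when a
#' degree bin is exhausted), summarised as mean and 5th/95th percentiles per
#' step.
#'
#' @param g undirected igraph.
#' @param targets ordered node names to remove (no duplicates).
#' @param n_random random baseline replicates (default 100).
#' @param seed RNG seed.
#' @return data.frame of class \code{ncb_disruption}: step, removed_id,
#'   n_components, giant_fraction, baseline_mean, baseline_p5, baseline_p95.
#' @export
disruption_profile <- function(g, targets, n_random = 100, seed = 1) {
  g <- graph_with_names(g)
  if (anyDuplicated(targets)) stop("duplicate targets")
  missing <- setdiff(targets, igraph::V(g)$name)
  if (length(missing)) stop("targets not in graph: ", paste(missing, collapse = ", "))
  n0 <- igraph::vcount(g)
  deg <- igraph::degree(g)

  removal_stats <- function(seq_ids) {
    gg <- g
    t(vapply(seq_along(seq_ids), function(i) {
      gg <<- igraph::delete_vertices(gg, seq_ids[i])
      comp <- igraph::components(gg)
      c(comp$no, max(comp$csize) / n0)
    }, numeric(2)))
  }

  # degree-matched random sequence: each target replaced by a non-target,
  # unused node with degree within +/- tol, widening tol one step at a time
  # when a bin is exhausted.  Targets themselves are excluded, otherwise
  # unique extreme-degree targets would be "matched" only by themselves and
  # the baseline would degenerate into the targeted removal.
  matched_sequence <- function() {
    used <- character(0)
    vapply(targets, function(tg) {
      tol <- 1
      repeat {
        cand <- setdiff(names(deg)[abs(deg - deg[tg]) <= tol], c(used, targets))
        if (length(cand)) break
        tol <- tol + 1
      }
      pick <- cand[sample.int(length(cand), 1L)]
      used <<- c(used, pick)
      pick
    }, character(1))
  }

  obs <- removal_stats(targets)
  base <- with_seed(seed, {
    replicate(n_random, removal_stats(matched_sequence())[, 2L])
  })
  base <- matrix(base, nrow = length(targets))
  out <- data.frame(
    step = seq_along(targets),
    removed_id = targets,
    n_components = obs[, 1L],
    giant_fraction = obs[, 2L],
    baseline_mean = rowMeans(base),
    baseline_p5 = apply(base, 1L, stats::quantile, probs = 0.05, names = FALSE),
    baseline_p95 = apply(base, 1L, stats::quantile, probs = 0.95, names = FALSE),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ncb_disruption", "data.frame")
  out
}

#' Rank ncRNA nodes by normalised brokerage
#'
#' ncRNA nodes sorted by normalised brokerage (descending), ties broken by
#' degree then node id; each entry carries its direct non-ncRNA interactors
#' (the node's functional-context gene set).  Isolated ncRNAs rank last with
#' brokerage 0.
#'
#' @param g a template network with \code{is_ncrna} vertex attribute.
#' @return data.frame: ncrna_id, biotype, normalized_brokerage, brokerage,
#'   degree, interactors (list column).
#' @export
rank_ncrna_brokers <- function(g) {
  g <- graph_with_names(g)
  is_nc <- igraph::V(g)$is_ncrna
  if (is.null(is_nc) || !any(is_nc)) {
    warning("no ncRNA nodes in network")
    return(data.frame(ncrna_id = character(0), biotype = character(0),
                      normalized_brokerage = numeric(0), brokerage = numeric(0),
                      degree = integer(0)))
  }
  nb <- normalized_brokerage(g)
  b <- brokerage(g)
  deg <- igraph::degree(g)
  ids <- igraph::V(g)$name[is_nc]
  ord <- order(-nb[ids], -deg[ids], ids)
  ids <- ids[ord]
  interactors <- lapply(ids, function(id) {
    nbh <- igraph::neighbors(g, id)$name
    sort(nbh[!igraph::V(g)[nbh]$is_ncrna])
  })
  out <- data.frame(
    ncrna_id = ids,
    biotype = igraph::V(g)[ids]$biotype %||% rep(NA_character_, length(ids)),
    normalized_brokerage = unname(nb[ids]),
    brokerage = unname(b[ids]),
    degree = unname(deg[ids]),
    stringsAsFactors = FALSE
  )
  out$interactors <- interactors
  out
}
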