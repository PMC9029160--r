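# Influence-function community landscape with overlapping modules.  This is
# a deliberately simplified landscape method: a damped random-walk influence
# matrix whose column sums form the landscape, local maxima ("hills") are
# module cores, and membership strengths are the influences exerted on the
# cores.  It trades the original per-link influence-zone construction for a
# deterministic, series-checkable operator.

#' Damped-spreading influence matrix
#'
#' influence(i -> j) is the total flow j receives when a unit perturbation
#' at i spreads along edges proportionally to edge weight, attenuated by
#' \code{damping} per step: the power series sum over t >= 0 of
#' damping^t P^t with P the (weight-proportional) row-stochastic transition
#' matrix.  The series is accumulated until the L1 change of an iteration
#' falls below \code{tol}; each row then sums to 1 / (1 - damping) on nodes
#' with at least one edge.
#'
#' @param g undirected igraph; the edge attribute \code{weight} is used for
#'   the spreading proportions when present, otherwise edges count equally.
#' @param damping per-step damping factor in (0, 1) (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-8).
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return dense node x node influence matrix with dimnames.
#' @export
influence_matrix <- function(g, damping = 0.85, tol = 1e-8, max_iter = 10000L) {
  if (damping <= 0 || damping >= 1) stop("damping must lie in (0, 1)")
  g <- graph_with_names(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE,
                                   attr = if (!is.null(igraph::E(g)$weight)) "weight" else NULL)
  nm <- igraph::V(g)$name
  dimnames(A) <- list(nm, nm)
  rs <- rowSums(A)
  P <- A / ifelse(rs == 0, 1, rs)
  n <- nrow(P)
  M <- diag(n)
  term <- diag(n)
  for (it in seq_len(max_iter)) {
    term <- damping * (term %*% P)
    M <- M + term
    if (sum(abs(term)) < tol) {
      dimnames(M) <- list(nm, nm)
      return(M)
    }
  }
  stop(sprintf("numerical error: influence series not converged in %d iterations (residual %.3g)",
               max_iter, sum(abs(term))))
}

#' Community landscape heights
#'
#' height(j) = sum over i of influence(i -> j): the total influence a node
#' receives from everywhere.  Hills (local maxima) of this field seed the
#' overlapping modules.
#'
#' @param influence matrix from \code{\link{influence_matrix}}.
#' @return named numeric vector of heights.
#' @export
community_landscape <- function(influence) {
  colSums(influence)
}

#' Detect hills and build the overlapping module landscape
#'
#' Module cores are the local maxima of the height field over the graph: a
#' node whose height is not exceeded by any neighbour, with exact ties
#' broken lexicographically by node id (the tied node with the smaller id
#' wins against its neighbours).  The membership strength of node n in the
#' module cored at c is influence(n -> c), normalised across cores so each
#' node's memberships sum to 1; modules overlap by construction.
#'
#' @param g the graph.
#' @param heights from \code{\link{community_landscape}}.
#' @param influence from \code{\link{influence_matrix}}.
#' @return object of class \code{ncb_landscape}: list with
#'   \code{membership} (node x module matrix), \code{landscape_height},
#'   \code{module_cores} (module id -> core node).
#' @export
detect_hills <- function(g, heights, influence) {
  g <- graph_with_names(g)
  nm <- igraph::V(g)$name
  is_core <- vapply(nm, function(v) {
    nb <- igraph::neighbors(g, v)$name
    if (length(nb) == 0L) return(TRUE)    # isolated node is its own hill
    all(heights[v] > heights[nb] |
          (heights[v] == heights[nb] & v < nb))
  }, logical(1))
  cores <- nm[is_core]
  module_ids <- paste0("module_", seq_along(cores))
  mem <- influence[, cores, drop = FALSE]
  rs <- rowSums(mem)
  mem <- mem / ifelse(rs == 0, 1, rs)
  colnames(mem) <- module_ids
  structure(list(
    membership = mem,
    landscape_height = heights,
    module_cores = stats::setNames(cores, module_ids)
  ), class = "ncb_landscape")
}

#' One-call module landscape
#'
#' @param g the graph.
#' @param damping,tol passed to \code{\link{influence_matrix}}.
#' @return an \code{ncb_landscape}.
#' @export
module_landscape <- function(g, damping = 0.85, tol = 1e-8) {
  inf <- influence_matrix(g, damping = damping, tol = tol)
  h <- community_landscape(inf)
  detect_hills(g, h, inf)
}

#' @export
print.ncb_landscape <- function(x, ...) {
  cat(sprintf("Module landscape: %d modules over %d nodes\n",
              ncol(x$membership), nrow(x$membership)))
  for (m in colnames(x$membership)) {
    size <- sum(x$membership[, m] > 0.1)
    cat(sprintf("  %s (core %s): %d nodes at strength > 0.1\n",
                m, x$module_cores[m], size))
  }
  invisible(x)
}

#' Shannon entropy of each node's module membership
#'
#' Broker-like nodes split their membership across modules and have higher
#' entropy than nodes buried inside one module.
#'
#' @param landscape an \code{ncb_landscape}.
#' @return named numeric vector (bits).
#' @export
membership_entropy <- function(landscape) {
  apply(landscape$membership, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
}

#' Module meta-graph
#'
#' One meta-level of the landscape hierarchy: modules become nodes and the
#' weight of a meta-edge is the summed cross-membership
#' sum_n min(m_na, m_nb) over all nodes n.
#'
#' @param landscape an \code{ncb_landscape}.
#' @return weighted undirected igraph over the modules.
#' @export
module_metagraph <- function(landscape) {
  mem <- landscape$membership
  k <- ncol(mem)
  ids <- colnames(mem)
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, k, name = ids)
  if (k > 1) {
    edges <- character(0); w <- numeric(0)
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        cw <- sum(pmin(mem[, a], mem[, b]))
        if (cw > 0) {
          edges <- c(edges, ids[a], ids[b])
          w <- c(w, cw)
        }
      }
    }
    if (length(w)) {
      g <- igraph::add_edges(g, edges)
      igraph::E(g)$weight <- w
    }
  }
  g
}

#' Write the membership matrix and module summary
#'
#' @param landscape an \code{ncb_landscape}.
#' @param dir output directory.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mf <- file.path(dir, "module_membership.tsv")
  df <- data.frame(node_id = rownames(landscape$membership),
                   landscape$membership, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- lapply(colnames(landscape$membership), function(m) {
    strengths <- landscape$membership[, m]
    top <- sort(strengths, decreasing = TRUE)
    list(module = m, core = unname(landscape$module_cores[m]),
         size_at_0.1 = sum(strengths > 0.1),
         top_members = as.list(round(top[seq_len(min(5, length(top)))], 4)))
  })
  jf <- file.path(dir, "module_summary.json")
  jsonlite::write_json(sm, jf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(membership = mf, summary = jf))
}
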