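# Independent brute-force oracles, written directly on adjacency matrices so
# they share no code with the package implementations.

adj_of <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A[A > 1] <- 1
  diag(A) <- 0
  A
}

oracle_clustering <- function(A, i) {
  nb <- which(A[i, ] == 1)
  k <- length(nb)
  if (k < 2) return(0)
  t <- 0
  for (a in seq_along(nb)) {
    for (b in seq_along(nb)) {
      if (a < b && A[nb[a], nb[b]] == 1) t <- t + 1
    }
  }
  2 * t / (k * (k - 1))
}

# Full Burt redundancy formula: S_i = sum_j (1 - sum_q p_iq m_jq), with
# p_iq the proportional tie strength of i to q and m_jq the marginal tie
# strength of j to q (binary graph: A_jq / max_k A_jk).
oracle_effective_size <- function(A, i) {
  nb <- which(A[i, ] == 1)
  k <- length(nb)
  if (k == 0) return(0)
  total <- 0
  for (j in nb) {
    red <- 0
    for (q in seq_len(nrow(A))) {
      if (q == i || q == j) next
      p_iq <- A[i, q] / sum(A[i, ])
      m_jq <- if (max(A[j, -j]) > 0) A[j, q] / max(A[j, -j]) else 0
      red <- red + p_iq * m_jq
    }
    total <- total + (1 - red)
  }
  total
}

# BFS all-pairs shortest path lengths on a 0/1 adjacency matrix.
oracle_spl <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1)) {
          if (dist[w] > d) {
            dist[w] <- d
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

oracle_local_efficiency <- function(A, i) {
  nb <- which(A[i, ] == 1)
  k <- length(nb)
  if (k < 2) return(0)
  sub <- A[nb, nb, drop = FALSE]
  D <- oracle_spl(sub)
  tot <- 0
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a < b) tot <- tot + 1 / D[a, b]
    }
  }
  tot / (k * (k - 1) / 2)
}

oracle_brokerage <- function(A, i) {
  k <- sum(A[i, ])
  if (k == 0) return(0)
  k - (k - 1) * oracle_local_efficiency(A, i)
}

count_components <- function(A) {
  n <- nrow(A)
  if (n == 0) return(0)
  seen <- rep(FALSE, n)
  comp <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(A[v, ] == 1 & !seen))
    }
  }
  comp
}

# remove-and-count definitions of cut vertices / cut edges
oracle_articulation <- function(A) {
  n <- nrow(A)
  base <- count_components(A)
  out <- integer(0)
  for (v in seq_len(n)) {
    B <- A[-v, -v, drop = FALSE]
    # removing v also removes an isolated-vertex component if v was isolated
    base_v <- base - as.integer(sum(A[v, ]) == 0)
    if (nrow(B) > 0 && count_components(B) > base_v) out <- c(out, v)
  }
  out
}

oracle_bridges <- function(A) {
  base <- count_components(A)
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      if (i < j && A[i, j] == 1) {
        B <- A
        B[i, j] <- B[j, i] <- 0
        if (count_components(B) > base) out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

# All non-isomorphic simple undirected graphs on exactly n nodes,
# deduplicated through canonical permutation.
enum_graphs <- function(n) {
  if (n == 1) return(list(igraph::make_empty_graph(1, directed = FALSE)))
  prs <- t(utils::combn(n, 2))
  ne <- nrow(prs)
  bits <- bitwShiftL(1L, 0:(ne - 1))
  seen <- new.env(hash = TRUE)
  out <- list()
  for (mask in 0:(2^ne - 1)) {
    sel <- which(bitwAnd(mask, bits) != 0L)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (length(sel)) g <- igraph::add_edges(g, t(prs[sel, , drop = FALSE]))
    gc <- igraph::permute(g, igraph::canonical_permutation(g)$labeling)
    el <- igraph::as_edgelist(gc)
    if (nrow(el)) {
      el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
      el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    }
    key <- paste0("k", paste(t(el), collapse = ","))
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

random_er_graph <- function(n, p, seed) {
  set.seed(seed)
  igraph::sample_gnp(n, p)
}

# direct MI computation from an explicit joint count table (bits),
# normalised by the smaller marginal entropy
oracle_mi_from_table <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  h <- function(v) -sum(v[v > 0] * log2(v[v > 0]))
  mi / min(h(px), h(py))
}
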