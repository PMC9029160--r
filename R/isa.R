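#' Iterative Signature Algorithm biclustering
#'
#' Runs the standard two-matrix ISA over a log2 expression matrix: samples
#' are scored by the current gene signature on the row-standardised matrix,
#' thresholded on |z|; genes are then scored by the retained samples on the
#' column-standardised matrix and thresholded on |z|; the alternation is
#' iterated to a fixed point.  Scores are signed and membership uses |z|
#' with sign coherence, so down-regulated signatures are found as readily as
#' up-regulated ones.  Each random sparse gene seed is run against every
#' (gene threshold, sample threshold) pair of the grid; converged fixed
#' points whose gene sets overlap with Jaccard > \code{dedup_jaccard} are
#' collapsed, keeping the higher-scoring one.
#'
#' Convergence: gene and sample membership both unchanged between
#' iterations, or the correlation of consecutive gene score vectors exceeds
#' 0.99 on two consecutive iterations.  Seeds that do not converge within
#' \code{max_iter} iterations are dropped; if none converge an empty set is
#' returned with a warning.
#'
#' @param x an \code{ncb_expr} on the log2 scale (typically the DE
#'   submatrix) or a plain numeric matrix.
#' @param gene_thresholds,sample_thresholds |z| threshold grids.
#' @param n_seeds random sparse gene seeds per threshold pair.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param max_iter iteration cap per seed.
#' @param seed_frac expected fraction of genes set in an initial seed.
#' @param dedup_jaccard gene-set Jaccard above which fixed points merge.
#' @param samples optional sample ids to restrict the matrix to.
#' @return object of class \code{ncb_biclusters}: list with
#'   \code{biclusters} (each with gene/sample ids, signed scores, threshold
#'   pair, raw score) and the grid used.
#' @export
isa_run <- function(x, gene_thresholds = seq(1.5, 3.0, by = 0.5),
                    sample_thresholds = seq(1.0, 2.0, by = 0.5),
                    n_seeds = 100, seed = 1, max_iter = 100,
                    seed_frac = 0.05, dedup_jaccard = 0.9, samples = NULL) {
  E <- if (inherits(x, "ncb_expr")) {
    if (x$scale != "log2") stop("isa_run expects log2-scale values")
    x$values
  } else {
    as.matrix(x)
  }
  if (!is.null(samples)) E <- E[, samples, drop = FALSE]
  if (is.null(rownames(E))) rownames(E) <- paste0("g", seq_len(nrow(E)))
  if (is.null(colnames(E))) colnames(E) <- paste0("s", seq_len(ncol(E)))

  rs <- row_sds(E)
  keep <- rs > 0
  if (!all(keep)) {
    if (!any(keep)) {
      warning("all rows are constant; no biclusters")
      return(empty_bicluster_set(gene_thresholds, sample_thresholds, n_seeds, seed))
    }
    E <- E[keep, , drop = FALSE]
    rs <- rs[keep]
  }
  Er <- (E - rowMeans(E)) / rs                      # rows z-scored: scores samples
  cs <- apply(E, 2L, stats::sd)
  cs[cs == 0] <- 1
  Ec <- t((t(E) - colMeans(E)) / cs)                # columns z-scored: scores genes
  ng <- nrow(E); ns <- ncol(E)

  grid <- expand.grid(tg = gene_thresholds, ts = sample_thresholds)
  fixed <- list()
  with_seed(seed, {
    seeds <- lapply(seq_len(n_seeds), function(i) {
      v <- stats::rbinom(ng, 1L, seed_frac)
      if (sum(v) == 0L) v[sample.int(ng, 1L)] <- 1L
      as.numeric(v)
    })
    for (si in seq_len(n_seeds)) {
      for (gi in seq_len(nrow(grid))) {
        bc <- isa_iterate(Er, Ec, seeds[[si]], grid$tg[gi], grid$ts[gi], max_iter)
        if (!is.null(bc)) {
          bc$seed_index <- si
          bc$seed_vector <- seeds[[si]]
          fixed[[length(fixed) + 1L]] <- bc
        }
      }
    }
  })
  if (length(fixed) == 0L) {
    warning("no ISA seed converged to a non-empty fixed point")
    return(empty_bicluster_set(gene_thresholds, sample_thresholds, n_seeds, seed))
  }
  # deduplicate, preferring higher raw score
  ord <- order(vapply(fixed, function(b) b$score, numeric(1)), decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    gi <- fixed[[i]]$genes
    dup <- any(vapply(kept, function(k) jaccard(gi, k$genes) > dedup_jaccard,
                      logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- fixed[[i]]
  }
  structure(list(biclusters = kept, gene_thresholds = gene_thresholds,
                 sample_thresholds = sample_thresholds, n_seeds = n_seeds,
                 seed = seed),
            class = "ncb_biclusters")
}

empty_bicluster_set <- function(gt, st, n_seeds, seed) {
  structure(list(biclusters = list(), gene_thresholds = gt,
                 sample_thresholds = st, n_seeds = n_seeds, seed = seed),
            class = "ncb_biclusters")
}

# One ISA run from a gene weight vector to a fixed point (or NULL).
isa_iterate <- function(Er, Ec, g, tg, ts, max_iter) {
  prev_genes <- integer(0); prev_samps <- integer(0)
  prev_score <- NULL
  stable_corr <- 0L
  for (it in seq_len(max_iter)) {
    s_score <- as.vector(crossprod(Er, g)) / sum(abs(g))
    z_s <- (s_score - mean(s_score)) / stats::sd(s_score)
    if (!is.finite(stats::sd(s_score)) || stats::sd(s_score) == 0) return(NULL)
    samp_keep <- which(abs(z_s) > ts)
    if (length(samp_keep) == 0L) return(NULL)
    w_s <- z_s[samp_keep]
    g_score <- as.vector(Ec[, samp_keep, drop = FALSE] %*% w_s) / sum(abs(w_s))
    sdg <- stats::sd(g_score)
    if (!is.finite(sdg) || sdg == 0) return(NULL)
    z_g <- (g_score - mean(g_score)) / sdg
    gene_keep <- which(abs(z_g) > tg)
    if (length(gene_keep) == 0L) return(NULL)

    converged <- identical(gene_keep, prev_genes) && identical(samp_keep, prev_samps)
    converged_by <- if (converged) "membership" else "correlation"
    if (!converged && !is.null(prev_score)) {
      if (stats::cor(g_score, prev_score) > 0.99) {
        stable_corr <- stable_corr + 1L
      } else {
        stable_corr <- 0L
      }
      if (stable_corr >= 2L) converged <- TRUE
    }
    if (converged) {
      gz <- z_g[gene_keep]; sz <- z_s[samp_keep]
      # Fixed-point strength: coherent mass of the sign-adjusted submatrix
      # per sqrt(cell count) -- a proxy for the leading singular value of
      # the bicluster, which grows with both size and per-cell coherence
      # and so separates real blocks from the coalitions ISA can always
      # carve out of noise.
      sub <- Er[gene_keep, samp_keep, drop = FALSE] * (sign(gz) %o% sign(sz))
      return(list(
        genes = rownames(Er)[gene_keep],
        samples = colnames(Er)[samp_keep],
        gene_scores = stats::setNames(gz, rownames(Er)[gene_keep]),
        sample_scores = stats::setNames(sz, colnames(Er)[samp_keep]),
        gene_threshold = tg, sample_threshold = ts,
        score = abs(sum(sub)) / sqrt(length(gene_keep) * length(samp_keep)),
        converged_by = converged_by,
        iterations = it
      ))
    }
    prev_genes <- gene_keep; prev_samps <- samp_keep; prev_score <- g_score
    g <- numeric(nrow(Er))
    g[gene_keep] <- z_g[gene_keep]
  }
  NULL
}

#' @export
print.ncb_biclusters <- function(x, ...) {
  cat(sprintf("ISA bicluster set: %d biclusters (grid %d gene x %d sample thresholds, %d seeds)\n",
              length(x$biclusters), length(x$gene_thresholds),
              length(x$sample_thresholds), x$n_seeds))
  for (i in seq_along(x$biclusters)) {
    b <- x$biclusters[[i]]
    cat(sprintf("  #%d: %d genes x %d samples, score %.1f%s\n", i,
                length(b$genes), length(b$samples), b$score,
                if (!is.null(b$robustness))
                  sprintf(", robustness %.1f (ratio %.2f)", b$robustness,
                          b$robustness_ratio) else ""))
  }
  invisible(x)
}

#' Robustness of a bicluster against matrix shuffling
#'
#' The bicluster's raw score (the coherent submatrix mass per sqrt cell at
#' the fixed point) is compared with the best score obtained by re-running
#' ISA from the same initial seed and thresholds on matrices whose rows and
#' columns have been independently shuffled, which destroys any joint
#' structure while keeping the marginals.  Both the raw score (the scale on
#' which tool-specific filters such as "robustness > 100" operate) and the
#' ratio to the shuffled maximum are returned; a bicluster carved out of
#' pure noise has a ratio near 1, and the default downstream filter keeps
#' fixed points that beat the shuffled ceiling (ratio above 1).
#'
#' @param bicluster one element of \code{ncb_biclusters$biclusters}.
#' @param x the matrix (or \code{ncb_expr}) the set was computed from.
#' @param n_shuffles number of shuffled matrices (>= 1).
#' @param seed RNG seed.
#' @param samples optional sample restriction matching the original run.
#' @param min_genes,min_samples size a shuffled fixed point must reach to
#'   count as a competitor; like-for-like comparison requires the same size
#'   constraint that is applied to the real biclusters, otherwise degenerate
#'   one-gene noise spikes dominate the shuffled score.
#' @return list with \code{score}, \code{shuffled_max} and \code{ratio}.
#' @export
isa_robustness <- function(bicluster, x, n_shuffles = 5, seed = 1, samples = NULL,
                           min_genes = 2, min_samples = 2) {
  if (n_shuffles < 1) stop("configuration error: n_shuffles must be >= 1")
  E <- if (inherits(x, "ncb_expr")) x$values else as.matrix(x)
  if (!is.null(samples)) E <- E[, samples, drop = FALSE]
  best <- 0
  with_seed(seed, {
    for (i in seq_len(n_shuffles)) {
      S <- E[sample(nrow(E)), sample(ncol(E))]
      S <- t(apply(S, 1L, sample))                  # break joint structure
      dimnames(S) <- dimnames(E)
      rs <- row_sds(S); rs[rs == 0] <- 1
      Sr <- (S - rowMeans(S)) / rs
      cs <- apply(S, 2L, stats::sd); cs[cs == 0] <- 1
      Sc <- t((t(S) - colMeans(S)) / cs)
      bc <- isa_iterate(Sr, Sc, bicluster$seed_vector,
                        bicluster$gene_threshold, bicluster$sample_threshold, 100L)
      if (!is.null(bc) && length(bc$genes) >= min_genes &&
          length(bc$samples) >= min_samples && bc$score > best) {
        best <- bc$score
      }
    }
  })
  list(score = bicluster$score, shuffled_max = best,
       ratio = if (best > 0) bicluster$score / best else Inf)
}

#' Attach robustness scores to every bicluster in a set
#'
#' @param set an \code{ncb_biclusters}.
#' @inheritParams isa_robustness
#' @return the set with \code{robustness} (raw score), \code{shuffled_max}
#'   and \code{robustness_ratio} stored per bicluster.
#' @export
add_robustness <- function(set, x, n_shuffles = 5, seed = 1, samples = NULL,
                           min_genes = 2, min_samples = 2) {
  stopifnot(inherits(set, "ncb_biclusters"))
  for (i in seq_along(set$biclusters)) {
    r <- isa_robustness(set$biclusters[[i]], x, n_shuffles = n_shuffles,
                        seed = seed + i, samples = samples,
                        min_genes = min_genes, min_samples = min_samples)
    set$biclusters[[i]]$robustness <- r$score
    set$biclusters[[i]]$shuffled_max <- r$shuffled_max
    set$biclusters[[i]]$robustness_ratio <- r$ratio
  }
  set
}

#' Size and robustness filter for bicluster sets
#'
#' Keeps biclusters with at least \code{min_genes} genes, \code{min_samples}
#' samples and a robustness at or above \code{min_robustness}, measured
#' either as the raw fixed-point score or as the ratio to the shuffled
#' maximum.
#'
#' @param set an \code{ncb_biclusters}.
#' @param min_genes,min_samples minimum dimensions (defaults 10 and 7).
#' @param min_robustness robustness cut-off (0 disables).
#' @param metric \code{"score"} (raw) or \code{"ratio"}.
#' @return the filtered \code{ncb_biclusters}.
#' @export
filter_biclusters <- function(set, min_genes = 10, min_samples = 7,
                              min_robustness = 0, metric = c("score", "ratio")) {
  stopifnot(inherits(set, "ncb_biclusters"))
  metric <- match.arg(metric)
  keep <- vapply(set$biclusters, function(b) {
    rob <- if (min_robustness > 0) {
      v <- if (metric == "score") b$robustness else b$robustness_ratio
      if (is.null(v)) stop("robustness not computed; run add_robustness() first")
      v >= min_robustness
    } else TRUE
    length(b$genes) >= min_genes && length(b$samples) >= min_samples && rob
  }, logical(1))
  set$biclusters <- set$biclusters[keep]
  set
}

#' Subtype composition of biclusters
#'
#' For each bicluster, the fraction of its member tumor samples carrying
#' each subtype label (or, with \code{by = "genes"} and a gene -> subtype
#' map, the fraction of member genes per subtype).  The dominant subtype and
#' its fraction are recorded per row.  Rows sum to 1 exactly on computed
#' data; a tolerance of about 0.02 applies only when encoding printed,
#' rounded tables via \code{\link{subtype_fraction_table}}.
#'
#' @param set an \code{ncb_biclusters}, or a list of bicluster-like lists
#'   with \code{samples} (and \code{genes}) elements.
#' @param subtype named character vector: tumor sample id -> subtype label
#'   (or gene id -> subtype when \code{by = "genes"}).
#' @param by count members by samples (default) or by genes.
#' @param group optional named vector (sample id -> normal/tumor); member
#'   samples labelled \code{"normal"} are excluded from the fractions, and
#'   any other member missing from \code{subtype} is an error naming it.
#'   Without \code{group}, every member must carry a subtype label.
#' @return a \code{ncb_subtype_fractions} data.frame: one row per bicluster,
#'   one column per subtype plus \code{dominant_subtype} and
#'   \code{dominant_fraction}.
#' @export
subtype_fractions <- function(set, subtype, by = c("samples", "genes"),
                              group = NULL) {
  by <- match.arg(by)
  bl <- if (inherits(set, "ncb_biclusters")) set$biclusters else set
  if (length(bl) == 0L) {
    return(subtype_fraction_table(matrix(numeric(0), 0, 0)))
  }
  levels <- sort(unique(unname(subtype)))
  rows <- vapply(bl, function(b) {
    members <- if (by == "samples") b$samples else b$genes
    if (by == "samples" && !is.null(group)) {
      members <- members[is.na(group[members]) | group[members] != "normal"]
    }
    unk <- setdiff(members, names(subtype))
    if (length(unk)) {
      stop("bicluster member(s) without subtype label: ",
           paste(unk, collapse = ", "))
    }
    if (length(members) == 0L) return(rep(NA_real_, length(levels)))
    tab <- table(factor(subtype[members], levels = levels))
    as.numeric(tab / sum(tab))
  }, numeric(length(levels)))
  rows <- if (is.null(dim(rows))) matrix(rows, ncol = 1L) else t(rows)
  colnames(rows) <- levels
  rownames(rows) <- paste0("#", seq_len(nrow(rows)))
  subtype_fraction_table(rows)
}

#' Encode a (possibly printed) bicluster-by-subtype fraction matrix
#'
#' Accepts a numeric matrix with bicluster rows and subtype columns, e.g. a
#' published table re-typed by hand; printed tables are rounded, so rows are
#' required to sum to 1 within 0.02.
#'
#' @param m numeric matrix, rows biclusters, columns subtypes.
#' @return data.frame of class \code{ncb_subtype_fractions} with
#'   \code{dominant_subtype}/\code{dominant_fraction} columns appended.
#' @export
subtype_fraction_table <- function(m) {
  m <- as.matrix(m)
  if (nrow(m)) {
    sums <- rowSums(m, na.rm = TRUE)
    ok <- is.na(rowSums(m)) | abs(sums - 1) <= 0.02
    if (!all(ok)) {
      stop("fraction rows must sum to 1 (within 0.02 for rounded tables); offending row(s): ",
           paste(which(!ok), collapse = ", "))
    }
  }
  df <- as.data.frame(m)
  if (nrow(m)) {
    dom <- apply(m, 1L, function(r) {
      if (all(is.na(r))) return(NA_integer_)
      which.max(r)
    })
    df$dominant_subtype <- ifelse(is.na(dom), NA_character_, colnames(m)[dom])
    df$dominant_fraction <- vapply(seq_len(nrow(m)), function(i) {
      if (is.na(dom[i])) NA_real_ else m[i, dom[i]]
    }, numeric(1))
  } else {
    df$dominant_subtype <- character(0)
    df$dominant_fraction <- numeric(0)
  }
  if (is.null(rownames(m)) && nrow(m)) rownames(df) <- paste0("#", seq_len(nrow(m)))
  class(df) <- c("ncb_subtype_fractions", "data.frame")
  df
}

#' Select signature biclusters by subtype dominance
#'
#' \code{strict} mode keeps biclusters whose dominant fraction exceeds
#' \code{threshold} (the "at least one prevalent subtype, > 50 percent"
#' rule); \code{top_per_subtype} returns, for each subtype, the single
#' bicluster maximising that subtype's fraction (the bold-cell convention
#' of published composition tables).
#'
#' @param table a \code{ncb_subtype_fractions}.
#' @param mode selection mode.
#' @param threshold dominance threshold for strict mode (default 0.5).
#' @return data.frame with columns \code{bicluster} (row label),
#'   \code{subtype} and \code{fraction}; zero rows when nothing qualifies.
#' @export
select_signature_biclusters <- function(table, mode = c("strict", "top_per_subtype"),
                                        threshold = 0.5) {
  stopifnot(inherits(table, "ncb_subtype_fractions"))
  mode <- match.arg(mode)
  empty <- data.frame(bicluster = character(0), subtype = character(0),
                      fraction = numeric(0), stringsAsFactors = FALSE)
  if (nrow(table) == 0L) return(empty)
  subtypes <- setdiff(colnames(table), c("dominant_subtype", "dominant_fraction"))
  if (mode == "strict") {
    keep <- which(!is.na(table$dominant_fraction) & table$dominant_fraction > threshold)
    if (length(keep) == 0L) return(empty)
    return(data.frame(bicluster = rownames(table)[keep],
                      subtype = table$dominant_subtype[keep],
                      fraction = table$dominant_fraction[keep],
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(subtypes, function(st) {
    col <- table[[st]]
    if (all(is.na(col))) return(NULL)
    i <- which.max(col)
    data.frame(bicluster = rownames(table)[i], subtype = st,
               fraction = col[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out %||% empty
}

#' Serialise a bicluster set to JSON
#'
#' @param set an \code{ncb_biclusters}.
#' @param path output file.
#' @export
write_biclusters_json <- function(set, path) {
  stopifnot(inherits(set, "ncb_biclusters"))
  payload <- list(
    gene_thresholds = set$gene_thresholds,
    sample_thresholds = set$sample_thresholds,
    n_seeds = set$n_seeds, seed = set$seed,
    biclusters = lapply(set$biclusters, function(b) {
      b[c("genes", "samples", "gene_scores", "sample_scores",
          "gene_threshold", "sample_threshold", "score",
          intersect(c("robustness", "robustness_ratio"), names(b)))]
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
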