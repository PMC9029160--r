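#' Expression matrix with sample and gene metadata
#'
#' Container for a gene x sample expression matrix together with the
#' metadata the pipeline needs downstream: a normal/tumor group label per
#' sample, a molecular-subtype label per tumor sample, and a biotype per
#' gene (protein_coding, pseudogene, antisense, lincRNA,
#' processed_transcript or repeat).  Values are either linear (FPKM-like,
#' non-negative) or log2; the scale is tracked so that normalisation and
#' differential expression are applied on the intended scale.
#'
#' @param values numeric matrix, genes as rows, samples as columns, with
#'   dimnames giving gene and sample identifiers.
#' @param group named character vector mapping every sample id to
#'   \code{"normal"} or \code{"tumor"}.
#' @param subtype named character vector mapping tumor sample ids to a
#'   subtype label.  Every tumor sample must be covered.
#' @param biotype named character vector mapping gene ids to a biotype.
#'   Genes missing from the map are labelled \code{"unannotated"}.
#' @param scale \code{"linear"} or \code{"log2"}.
#' @param pseudocount the pseudocount used (or to be used) in the log2
#'   transform; retained so linear values can be recovered.
#' @return an object of class \code{ncb_expr}.
#' @export
expression_matrix <- function(values, group, subtype = character(), biotype = NULL,
                              scale = c("linear", "log2"), pseudocount = 1) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene row names and sample column names")
  }
  if (anyNA(values)) stop("expression values must not contain missing entries")
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale expression values must be non-negative")
  }
  samples <- colnames(values)
  if (!all(samples %in% names(group))) {
    stop("every sample needs a group label (normal/tumor)")
  }
  group <- group[samples]
  if (!all(group %in% c("normal", "tumor"))) {
    stop("group labels must be 'normal' or 'tumor'")
  }
  tum <- samples[group == "tumor"]
  missing_st <- setdiff(tum, names(subtype))
  if (length(tum) && length(missing_st)) {
    stop("tumor samples without a subtype label: ", paste(missing_st, collapse = ", "))
  }
  genes <- rownames(values)
  bt <- rep("unannotated", length(genes))
  names(bt) <- genes
  if (!is.null(biotype)) {
    known <- intersect(genes, names(biotype))
    bt[known] <- biotype[known]
  }
  vocab <- c("protein_coding", "pseudogene", "antisense", "lincRNA",
             "processed_transcript", "repeat", "unannotated")
  if (!all(bt %in% vocab)) {
    stop("unknown biotype label(s): ", paste(setdiff(bt, vocab), collapse = ", "))
  }
  structure(list(
    values = values,
    gene_ids = genes,
    sample_ids = samples,
    group = group,
    subtype = subtype[intersect(names(subtype), tum)],
    biotype = bt,
    scale = scale,
    pseudocount = pseudocount
  ), class = "ncb_expr")
}

#' @export
print.ncb_expr <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  groups: %d normal, %d tumor\n",
              sum(x$group == "normal"), sum(x$group == "tumor")))
  if (length(x$subtype)) {
    tab <- table(x$subtype)
    cat("  subtypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  tab <- table(x$biotype)
  cat("  biotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ncb_expr <- function(x) dim(x$values)

# Linear-scale copy of the values, inverting the log2 transform if needed.
linear_values <- function(x) {
  if (x$scale == "linear") return(x$values)
  pmax(2^x$values - x$pseudocount, 0)
}

#' Quantile normalisation
#'
#' Forces every sample (column) to share the same empirical distribution:
#' each column's sorted values are replaced by the across-column rank means.
#' Ties share the mean of the rank means they span.  The heavy lifting is
#' done by \code{limma::normalizeQuantiles}; gene and sample order are
#' preserved.  Idempotent: a second application changes nothing.
#'
#' @param x an \code{ncb_expr} on the linear scale.
#' @return the normalised \code{ncb_expr}, still linear scale.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "ncb_expr"))
  if (x$scale != "linear") stop("quantile_normalize expects linear-scale values")
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  x$values <- v
  x
}

#' Log2 transform with pseudocount
#'
#' @param x an \code{ncb_expr} on the linear scale.
#' @param pseudocount positive offset added before taking log2 (default 1,
#'   so a zero stays zero).
#' @return the transformed \code{ncb_expr} with the scale flag set.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "ncb_expr"))
  if (x$scale != "linear") stop("matrix is already on the log2 scale")
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("`pseudocount` must be positive")
  }
  if (any(x$values < 0)) stop("negative values cannot be log2-transformed")
  x$values <- log2(x$values + pseudocount)
  x$scale <- "log2"
  x$pseudocount <- pseudocount
  x
}

#' Two-sample differential expression (tumor vs normal)
#'
#' Per-gene two-sample t-test on log2 values, tumor minus normal.  The
#' default is the pooled-variance Student test; \code{welch = TRUE} switches
#' to the unequal-variance form.  The fold-change gate is two-sided:
#' \code{|log2FC| >= log2(fc_threshold)}.  The coefficient of variation is
#' computed on the linear scale across all samples, and genes with cv = 0
#' (flat profiles) never pass.  No multiple-testing correction is applied by
#' default, matching a raw p-value filter; \code{adjust = "BH"} gates on
#' Benjamini-Hochberg adjusted p-values instead.
#'
#' A gene that is constant within both groups has an undefined t statistic;
#' it is reported with t = 0 and p = 1 when the group means agree (and with
#' p = 0 when they differ, which can only happen on degenerate input).
#'
#' @param x an \code{ncb_expr} on the log2 scale with both groups present.
#' @param p_threshold p-value cut-off (default 0.001).
#' @param fc_threshold linear fold-change cut-off (default 2).
#' @param welch use the Welch unequal-variance test instead of pooled.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return a data.frame with one row per gene: gene_id, biotype,
#'   t_statistic, p_value, p_adjusted, log2_fc, cv, passes.
#' @export
differential_expression <- function(x, p_threshold = 0.001, fc_threshold = 2,
                                    welch = FALSE, adjust = c("none", "BH")) {
  stopifnot(inherits(x, "ncb_expr"))
  adjust <- match.arg(adjust)
  if (x$scale != "log2") stop("differential_expression expects log2-scale values")
  idx_t <- which(x$group == "tumor")
  idx_n <- which(x$group == "normal")
  n1 <- length(idx_t); n0 <- length(idx_n)
  if (n1 < 2L || n0 < 2L) stop("both groups need at least 2 samples")
  vt <- x$values[, idx_t, drop = FALSE]
  vn <- x$values[, idx_n, drop = FALSE]
  m1 <- rowMeans(vt); m0 <- rowMeans(vn)
  v1 <- row_sds(vt)^2; v0 <- row_sds(vn)^2
  diff <- m1 - m0
  if (welch) {
    se2 <- v1 / n1 + v0 / n0
    tstat <- diff / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    tstat <- diff / sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(tstat))
  }
  pval <- 2 * stats::pt(-abs(tstat), df)
  degen <- !is.finite(tstat)
  if (any(degen)) {
    zero_diff <- degen & abs(diff) < .Machine$double.eps^0.5
    tstat[zero_diff] <- 0
    pval[zero_diff] <- 1
    tstat[degen & !zero_diff] <- sign(diff[degen & !zero_diff]) * Inf
    pval[degen & !zero_diff] <- 0
  }
  lin <- linear_values(x)
  mu <- rowMeans(lin)
  cv <- ifelse(mu > 0, apply(lin, 1L, stats::sd) / mu, 0)
  padj <- if (adjust == "BH") stats::p.adjust(pval, method = "BH") else pval
  gate_p <- if (adjust == "BH") padj else pval
  passes <- gate_p <= p_threshold & abs(diff) >= log2(fc_threshold) & cv > 0
  data.frame(
    gene_id = x$gene_ids,
    biotype = unname(x$biotype[x$gene_ids]),
    t_statistic = unname(tstat),
    p_value = unname(pval),
    p_adjusted = unname(padj),
    log2_fc = unname(diff),
    cv = unname(cv),
    passes = unname(passes),
    stringsAsFactors = FALSE
  )
}

#' Partition passing genes by biotype
#'
#' @param de data.frame from \code{differential_expression}.
#' @param biotype optional named character vector overriding the biotypes
#'   recorded in \code{de}; genes missing from it are reported under
#'   \code{"unannotated"} rather than dropped.
#' @return named list biotype -> character vector of passing gene ids, with
#'   a \code{counts} attribute.
#' @export
biotype_partition <- function(de, biotype = NULL) {
  stopifnot(is.data.frame(de), all(c("gene_id", "passes") %in% names(de)))
  hits <- de[de$passes, , drop = FALSE]
  if (nrow(hits) == 0L) {
    out <- list()
    attr(out, "counts") <- integer()
    return(out)
  }
  bt <- if (is.null(biotype)) {
    hits$biotype
  } else {
    b <- unname(biotype[hits$gene_id])
    b[is.na(b)] <- "unannotated"
    b
  }
  out <- split(hits$gene_id, bt)
  out <- out[order(names(out))]
  attr(out, "counts") <- vapply(out, length, integer(1))
  out
}

#' Read / write the expression TSV formats
#'
#' Matrix TSV: genes as rows, first column \code{gene_id}, remaining columns
#' one per sample.  Metadata TSV: columns \code{sample_id}, \code{group},
#' \code{subtype} (empty for normals).  Biotype TSV: columns \code{gene_id},
#' \code{biotype}.
#'
#' @param matrix_file,meta_file,biotype_file file paths.
#' @param scale scale flag of the stored values.
#' @return an \code{ncb_expr}.
#' @export
read_expression_tsv <- function(matrix_file, meta_file, biotype_file = NULL,
                                scale = "linear") {
  m <- utils::read.delim(matrix_file, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(m[, -1, drop = FALSE])
  rownames(vals) <- m[[1]]
  meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  group <- stats::setNames(meta$group, meta$sample_id)
  st <- meta$subtype
  keep <- !is.na(st) & nzchar(st)
  subtype <- stats::setNames(st[keep], meta$sample_id[keep])
  biotype <- NULL
  if (!is.null(biotype_file)) {
    bt <- utils::read.delim(biotype_file, stringsAsFactors = FALSE)
    biotype <- stats::setNames(bt$biotype, bt$gene_id)
  }
  expression_matrix(vals, group, subtype, biotype, scale = scale)
}

#' @rdname read_expression_tsv
#' @param x an \code{ncb_expr}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_expression_tsv <- function(x, dir, prefix = "expression") {
  stopifnot(inherits(x, "ncb_expr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mf <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- rep("", length(x$sample_ids))
  names(st) <- x$sample_ids
  st[names(x$subtype)] <- x$subtype
  meta <- data.frame(sample_id = x$sample_ids, group = unname(x$group),
                     subtype = unname(st), stringsAsFactors = FALSE)
  mef <- file.path(dir, paste0(prefix, "_meta.tsv"))
  utils::write.table(meta, mef, sep = "\t", quote = FALSE, row.names = FALSE)
  btf <- file.path(dir, paste0(prefix, "_biotype.tsv"))
  bt <- data.frame(gene_id = x$gene_ids, biotype = unname(x$biotype),
                   stringsAsFactors = FALSE)
  utils::write.table(bt, btf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = mf, meta = mef, biotype = btf))
}
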