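# Small expression fixtures built in code.

tiny_expr <- function(values, n_normal, n_tumor, subtypes = NULL, biotype = NULL) {
  samples <- c(sprintf("N%02d", seq_len(n_normal)), sprintf("T%02d", seq_len(n_tumor)))
  colnames(values) <- samples
  group <- stats::setNames(rep(c("normal", "tumor"), c(n_normal, n_tumor)), samples)
  tum <- samples[group == "tumor"]
  st <- if (is.null(subtypes)) {
    stats::setNames(rep("basal", length(tum)), tum)
  } else {
    stats::setNames(subtypes, tum)
  }
  expression_matrix(values, group, st, biotype, scale = "linear")
}

# matrix of independent log-normal noise with named genes
noise_expr <- function(n_genes, n_normal, n_tumor, seed, sd = 1) {
  set.seed(seed)
  v <- 2^matrix(rnorm(n_genes * (n_normal + n_tumor), 5, sd), nrow = n_genes,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)), NULL))
  tiny_expr(v, n_normal, n_tumor)
}

published_fractions <- function() {
  path <- system.file("extdata", "published_subtype_fractions.tsv", package = "ncbroker")
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$bicluster
  subtype_fraction_table(m)
}
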