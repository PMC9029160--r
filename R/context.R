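# Per-ncRNA functional-context reports: join broker rankings, module
# memberships and optional user-supplied annotation / correlation tables.
# Annotation and correlation values are pass-through only; nothing is
# computed from external services.

#' Build per-ncRNA broker contexts
#'
#' One context per ranked ncRNA that has at least one surviving edge, in
#' ranking order.  ncRNAs with zero surviving edges are excluded from the
#' contexts and listed in the \code{isolated} attribute.  Optional tables
#' are joined by gene id and echoed unchanged; annotation rows referencing
#' genes absent from the network trigger a warning but are kept.
#'
#' @param network a template network.
#' @param landscape an \code{ncb_landscape} computed on it.
#' @param ranking data.frame from \code{\link{rank_ncrna_brokers}}.
#' @param annotations optional data.frame (gene_id, term).
#' @param correlations optional data.frame (gene_id, rho, p, adj_p).
#' @return list of contexts (class \code{ncb_contexts}); each context has
#'   ncrna_id, biotype, normalized_brokerage, interactors, modules (named
#'   strengths), and optional annotations / correlations for interactors.
#' @export
build_contexts <- function(network, landscape, ranking,
                           annotations = NULL, correlations = NULL) {
  if (nrow(ranking) == 0L) stop("ranking is empty")
  if (!is.null(annotations)) {
    unknown <- setdiff(annotations$gene_id, igraph::V(network)$name)
    if (length(unknown)) {
      warning("annotation rows reference genes outside the network: ",
              paste(unique(unknown), collapse = ", "))
    }
  }
  isolated <- ranking$ncrna_id[ranking$degree == 0]
  active <- ranking[ranking$degree > 0, , drop = FALSE]
  contexts <- lapply(seq_len(nrow(active)), function(i) {
    id <- active$ncrna_id[i]
    genes <- active$interactors[[i]]
    mods <- landscape$membership[id, ]
    mods <- sort(mods[mods > 0], decreasing = TRUE)
    ctx <- list(
      ncrna_id = id,
      biotype = active$biotype[i],
      normalized_brokerage = active$normalized_brokerage[i],
      interactors = genes,
      modules = as.list(mods)
    )
    if (!is.null(annotations)) {
      ann <- annotations[annotations$gene_id %in% genes, , drop = FALSE]
      ctx$annotations <- split(ann$term, ann$gene_id)
    }
    if (!is.null(correlations)) {
      cr <- correlations[correlations$gene_id %in% genes, , drop = FALSE]
      rownames(cr) <- NULL
      ctx$correlations <- cr
    }
    ctx
  })
  structure(contexts, class = "ncb_contexts", isolated = isolated)
}

#' Render broker-context reports
#'
#' Writes the contexts in a stable field order.  TSV: one row per ncRNA with
#' semicolon-collapsed interactor and module fields (round-trippable);
#' JSON: full structure; markdown: per-broker narrative (broker ->
#' interactors -> contexts) with the isolated appendix.
#'
#' @param contexts an \code{ncb_contexts}.
#' @param format one of \code{"tsv"}, \code{"json"}, \code{"markdown"}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
render_report <- function(contexts, format = c("tsv", "json", "markdown"), path) {
  format <- match.arg(format)
  isolated <- attr(contexts, "isolated") %||% character(0)
  if (format == "tsv") {
    df <- data.frame(
      ncrna_id = vapply(contexts, `[[`, character(1), "ncrna_id"),
      biotype = vapply(contexts, `[[`, character(1), "biotype"),
      normalized_brokerage = vapply(contexts, `[[`, numeric(1), "normalized_brokerage"),
      interactors = vapply(contexts, function(c) paste(c$interactors, collapse = ";"),
                           character(1)),
      modules = vapply(contexts, function(c) {
        paste(sprintf("%s=%.6g", names(c$modules), unlist(c$modules)), collapse = ";")
      }, character(1)),
      stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "json") {
    payload <- list(contexts = lapply(unclass(contexts), identity),
                    isolated = as.list(isolated))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    lines <- c("# ncRNA broker contexts", "")
    for (ctx in contexts) {
      lines <- c(lines,
                 sprintf("## %s (%s, normalized brokerage %.3f)",
                         ctx$ncrna_id, ctx$biotype, ctx$normalized_brokerage),
                 "",
                 sprintf("Interactors: %s", paste(ctx$interactors, collapse = ", ")),
                 sprintf("Modules: %s",
                         paste(sprintf("%s (%.3f)", names(ctx$modules),
                                       unlist(ctx$modules)), collapse = ", ")))
      if (!is.null(ctx$correlations) && nrow(ctx$correlations)) {
        lines <- c(lines, "", "External correlations:")
        lines <- c(lines, apply(ctx$correlations, 1L, function(r) {
          paste0("- ", paste(r, collapse = " / "))
        }))
      }
      lines <- c(lines, "")
    }
    if (length(isolated)) {
      lines <- c(lines, "## Isolated ncRNAs", "",
                 paste("-", isolated))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read the optional annotation / correlation tables
#'
#' Annotation TSV: columns gene_id, term.  Correlation TSV: columns gene_id,
#' rho, p, adj_p (mirroring published RNA-protein correlation tables).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_annotation_tsv
#' @export
read_correlation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "rho", "p", "adj_p")
  if (!all(need %in% names(df))) {
    stop("correlation table needs columns: ", paste(need, collapse = ", "))
  }
  df
}
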