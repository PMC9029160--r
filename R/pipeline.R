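#' Control parameters for the broker-inference pipeline
#'
#' Collects every stage parameter with its default: differential expression
#' at raw p <= 0.001 and fold change >= 2, ISA bicluster filtering at 10
#' genes x 7 samples, 1000 permutation draws and 100 bootstrap
#' randomizations for the network stage.  Robustness filtering defaults to
#' the shuffled-matrix ratio (a fixed point must beat the best fixed point
#' found on shuffled data); raw-score filtering is available for parity
#' with tool-specific scales.
#'
#' @param p_threshold,fc_threshold,welch,pseudocount DE stage.
#' @param gene_thresholds,sample_thresholds,n_seeds,seed_frac,dedup_jaccard
#'   ISA stage.
#' @param isa_samples \code{"tumor"} (default), \code{"normal"} or
#'   \code{"all"}: biclustering is run separately per group, and the tumor
#'   run is the one whose biclusters carry subtype composition.
#' @param n_shuffles,min_robustness,robustness_metric robustness filter.
#' @param min_genes,min_samples bicluster size filter.
#' @param selection_mode,dominance_threshold signature-bicluster selection.
#' @param alpha,min_persistence,n_perm,n_boot,n_bins,network_samples,metric,correction
#'   network stage; see \code{\link{build_template_network}}.
#' @param damping module landscape.
#' @param top_n brokers carried into the disruption stage.
#' @param n_random random-baseline replicates for disruption.
#' @return named list of class \code{ncbroker_control}.
#' @export
ncbroker_control <- function(p_threshold = 0.001, fc_threshold = 2,
                             welch = FALSE, pseudocount = 1,
                             gene_thresholds = seq(1.5, 3.0, by = 0.5),
                             sample_thresholds = seq(1.0, 2.0, by = 0.5),
                             n_seeds = 100, seed_frac = 0.05, dedup_jaccard = 0.9,
                             isa_samples = "tumor",
                             n_shuffles = 5, min_robustness = 1,
                             robustness_metric = "ratio",
                             min_genes = 10, min_samples = 7,
                             selection_mode = "strict", dominance_threshold = 0.5,
                             alpha = 0.05, min_persistence = 0.8,
                             n_perm = 1000, n_boot = 100, n_bins = NULL,
                             network_samples = "tumor", metric = "mi",
                             correction = "family",
                             damping = 0.85, top_n = 5, n_random = 100) {
  ctl <- as.list(environment())
  class(ctl) <- "ncbroker_control"
  ctl
}

pipeline_stages <- c("normalize", "de", "isa", "robustness", "select",
                     "network", "topology", "modules", "context")

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Fit the ncRNA broker-inference pipeline
#'
#' The main entry point: takes an expression cohort and runs the full
#' inference chain -- quantile/log2 normalisation, tumor-vs-normal
#' differential expression, ISA biclustering with robustness scoring and
#' subtype-dominance selection, the mutual-information template network over
#' the signature genes with the differentially expressed ncRNAs embedded,
#' the topology battery with brokerage ranking, the overlapping module
#' landscape, targeted broker-removal disruption against a degree-matched
#' random baseline, and the per-ncRNA context reports.
#'
#' All randomness derives from the single \code{seed}; per-stage seeds are
#' derived deterministically from it, so any stage can be reproduced in
#' isolation.
#'
#' @param x an \code{\link{expression_matrix}} (linear FPKM-like values) or
#'   the result list of \code{\link{simulate_expression}}.
#' @param control an \code{\link{ncbroker_control}}.
#' @param seed master integer seed.
#' @param annotations,correlations optional pass-through tables for the
#'   context reports.
#' @return an object of class \code{ncbroker}; see
#'   \code{\link{summary.ncbroker}}.  Components: \code{expr} (normalised),
#'   \code{de}, \code{biotype_sets}, \code{biclusters}, \code{fractions},
#'   \code{selection}, \code{network}, \code{topology}, \code{landscape},
#'   \code{ranking}, \code{disruption}, \code{contexts}.
#' @export
ncbroker <- function(x, control = ncbroker_control(), seed = 1,
                     annotations = NULL, correlations = NULL) {
  if (is.list(x) && !inherits(x, "ncb_expr") && !is.null(x$expr)) x <- x$expr
  stopifnot(inherits(x, "ncb_expr"), inherits(control, "ncbroker_control"))
  cl <- match.call()

  norm <- run_stage("normalize", {
    if (x$scale == "linear") {
      log2_transform(quantile_normalize(x), pseudocount = control$pseudocount)
    } else {
      x
    }
  })
  # The network stage works from the un-normalised log2 profiles: the MI
  # estimator bins each gene across samples, so it is invariant to any
  # monotone per-gene rescaling and gains nothing from quantile
  # normalisation -- while across-sample quantile normalisation perturbs
  # every profile through the shared column ranks and induces weak
  # artifactual dependence between unrelated genes of similar abundance.
  raw_log2 <- if (x$scale == "linear") {
    log2_transform(x, pseudocount = control$pseudocount)
  } else {
    x
  }

  de <- run_stage("de", differential_expression(
    norm, p_threshold = control$p_threshold, fc_threshold = control$fc_threshold,
    welch = control$welch))
  biotype_sets <- biotype_partition(de)
  passing <- de$gene_id[de$passes]
  if (length(passing) < control$min_genes) {
    stop("stage 'de' failed: fewer passing genes (", length(passing),
         ") than min_genes", call. = FALSE)
  }

  nc_biotypes <- c("pseudogene", "antisense", "lincRNA", "processed_transcript",
                   "repeat")
  ncrna_ids <- de$gene_id[de$passes & de$biotype %in% nc_biotypes]

  de_expr <- norm
  de_expr$values <- norm$values[passing, , drop = FALSE]
  de_expr$gene_ids <- passing
  de_expr$biotype <- norm$biotype[passing]

  isa_ids <- switch(control$isa_samples,
                    all = NULL,
                    tumor = names(norm$group)[norm$group == "tumor"],
                    normal = names(norm$group)[norm$group == "normal"],
                    stop("configuration error: isa_samples must be all/tumor/normal"))
  bset <- run_stage("isa", isa_run(
    de_expr, gene_thresholds = control$gene_thresholds,
    sample_thresholds = control$sample_thresholds,
    n_seeds = control$n_seeds, seed = stage_seed(seed, "isa"),
    seed_frac = control$seed_frac, dedup_jaccard = control$dedup_jaccard,
    samples = isa_ids))
  # size filter first so robustness is only scored for eligible biclusters
  bset <- filter_biclusters(bset, min_genes = control$min_genes,
                            min_samples = control$min_samples)
  bset <- run_stage("robustness", add_robustness(
    bset, de_expr, n_shuffles = control$n_shuffles,
    seed = stage_seed(seed, "robustness"), samples = isa_ids,
    min_genes = control$min_genes, min_samples = control$min_samples))
  bset <- filter_biclusters(bset, min_genes = control$min_genes,
                            min_samples = control$min_samples,
                            min_robustness = control$min_robustness,
                            metric = control$robustness_metric)

  fractions <- run_stage("select", subtype_fractions(bset, norm$subtype,
                                                     group = norm$group))
  selection <- select_signature_biclusters(fractions,
                                           mode = control$selection_mode,
                                           threshold = control$dominance_threshold)
  sel_idx <- match(selection$bicluster, rownames(fractions))
  sig_genes <- sort(unique(unlist(lapply(bset$biclusters[sel_idx], `[[`, "genes"))))
  sig_genes <- setdiff(sig_genes, ncrna_ids)
  if (length(sig_genes) == 0L) {
    stop("stage 'select' failed: no signature bicluster genes to build the network from",
         call. = FALSE)
  }

  net <- run_stage("network", build_template_network(
    raw_log2, genes = sig_genes, ncrna = ncrna_ids, alpha = control$alpha,
    min_persistence = control$min_persistence, n_perm = control$n_perm,
    n_boot = control$n_boot, n_bins = control$n_bins,
    samples = control$network_samples, seed = stage_seed(seed, "network"),
    metric = control$metric, de = de, correction = control$correction))

  topo <- run_stage("topology", node_topology(net))
  ranking <- run_stage("topology", rank_ncrna_brokers(net))
  landscape <- run_stage("modules", module_landscape(net, damping = control$damping))

  targets <- ranking$ncrna_id[ranking$degree > 0]
  targets <- targets[seq_len(min(control$top_n, length(targets)))]
  disruption <- if (length(targets)) {
    run_stage("topology", disruption_profile(net, targets,
                                             n_random = control$n_random,
                                             seed = stage_seed(seed, "disrupt")))
  } else {
    NULL
  }

  contexts <- if (nrow(ranking)) {
    run_stage("context", build_contexts(net, landscape, ranking,
                                        annotations = annotations,
                                        correlations = correlations))
  } else {
    structure(list(), class = "ncb_contexts", isolated = character(0))
  }

  structure(list(
    call = cl, expr = norm, de = de, biotype_sets = biotype_sets,
    biclusters = bset, fractions = fractions, selection = selection,
    network = net, topology = topo, landscape = landscape, ranking = ranking,
    disruption = disruption, contexts = contexts,
    control = control, seed = seed
  ), class = "ncbroker")
}

#' @export
print.ncbroker <- function(x, ...) {
  cat("ncRNA broker inference\n")
  cat(sprintf("  DE genes passing (p <= %g, FC >= %g): %d (%d non-coding)\n",
              x$control$p_threshold, x$control$fc_threshold,
              sum(x$de$passes),
              sum(x$de$passes & x$de$biotype != "protein_coding")))
  cat(sprintf("  biclusters kept: %d; signature biclusters: %d\n",
              length(x$biclusters$biclusters), nrow(x$selection)))
  cat(sprintf("  template network: %d nodes, %d edges (metric %s)\n",
              igraph::vcount(x$network), igraph::ecount(x$network),
              igraph::graph_attr(x$network, "metric")))
  top <- utils::head(x$ranking, 5)
  if (nrow(top)) {
    cat("  top brokers:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %d. %s (%s) normalized brokerage %.3f, degree %d\n",
                  i, top$ncrna_id[i], top$biotype[i],
                  top$normalized_brokerage[i], top$degree[i]))
    }
  }
  invisible(x)
}

#' Summarise a fitted broker inference
#'
#' @param object an \code{ncbroker}.
#' @param ... unused.
#' @return list of class \code{summary.ncbroker} with DE counts by biotype,
#'   the subtype-fraction table, the broker ranking and the disruption
#'   profile.
#' @export
summary.ncbroker <- function(object, ...) {
  s <- list(
    de_counts = attr(object$biotype_sets, "counts"),
    n_biclusters = length(object$biclusters$biclusters),
    fractions = object$fractions,
    selection = object$selection,
    n_nodes = igraph::vcount(object$network),
    n_edges = igraph::ecount(object$network),
    ranking = object$ranking,
    disruption = object$disruption
  )
  class(s) <- "summary.ncbroker"
  s
}

#' @export
print.summary.ncbroker <- function(x, ...) {
  cat("Differentially expressed genes by biotype:\n")
  print(x$de_counts)
  cat(sprintf("\nBiclusters kept: %d; subtype fractions:\n", x$n_biclusters))
  print(as.data.frame(x$fractions), digits = 3)
  cat("\nSignature biclusters:\n"); print(x$selection)
  cat(sprintf("\nNetwork: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat("\nncRNA broker ranking:\n")
  print(x$ranking[, setdiff(names(x$ranking), "interactors")], digits = 3)
  if (!is.null(x$disruption)) {
    cat("\nDisruption profile (targeted vs degree-matched random baseline):\n")
    print(as.data.frame(x$disruption), digits = 3)
  }
  invisible(x)
}

#' Diagnostic plots for a fitted broker inference
#'
#' Two base-graphics panels: the edge persistence histogram (rewiring
#' strength of the retained edges) and brokerage against degree with ncRNA
#' nodes highlighted.
#'
#' @param x an \code{ncbroker}.
#' @param ... passed to \code{par}.
#' @export
plot.ncbroker <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), ...)
  on.exit(graphics::par(op))
  pers <- igraph::E(x$network)$persistence
  if (length(pers)) {
    graphics::hist(pers, breaks = seq(0, 1, by = 0.05), col = "grey70",
                   main = "Edge persistence", xlab = "bootstrap persistence")
  } else {
    graphics::plot.new(); graphics::title("Edge persistence (no edges)")
  }
  tp <- x$topology
  is_nc <- tp$node_id %in% x$ranking$ncrna_id
  graphics::plot(tp$degree, tp$brokerage,
                 col = ifelse(is_nc, "red3", "grey40"),
                 pch = ifelse(is_nc, 17, 1),
                 xlab = "degree k", ylab = "brokerage B = k - (k-1)E",
                 main = "Brokerage vs degree")
  graphics::legend("topleft", legend = c("ncRNA", "gene"),
                   col = c("red3", "grey40"), pch = c(17, 1), bty = "n")
  invisible(x)
}

# ---- file-based orchestration -------------------------------------------

default_pipeline_config <- function() {
  list(seed = 1, outdir = "ncbroker_run",
       input = NULL, simulate = NULL,
       params = as.list(unclass(ncbroker_control())))
}

#' Normalise a pipeline configuration
#'
#' Fills every missing stage parameter with its default so the effective
#' configuration is fully explicit; round-trips through YAML unchanged.
#'
#' @param config list or path to a YAML file with optional keys
#'   \code{seed}, \code{outdir}, \code{input} (matrix/meta/biotype paths),
#'   \code{simulate} (arguments of \code{\link{sim_config}}) and
#'   \code{params} (arguments of \code{\link{ncbroker_control}}).
#' @return the default-filled config list.
#' @export
normalize_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- default_pipeline_config()
  out <- utils::modifyList(def, config, keep.null = TRUE)
  known <- names(formals(ncbroker_control))
  unknown <- setdiff(names(out$params), known)
  if (length(unknown)) {
    stop("configuration error: unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  out
}

config_hash <- function(params) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  dp <- vapply(params[order(names(params))], function(v) {
    paste(deparse(v), collapse = " ")
  }, character(1))
  writeLines(paste(names(dp), dp, sep = "="), tf)
  unname(tools::md5sum(tf))
}

#' Run the pipeline from a configuration, writing a run directory
#'
#' Executes the full workflow from either input files or a simulate block,
#' writing every intermediate artifact (normalised matrix, DE table,
#' bicluster JSON, subtype-fraction table, GraphML network and edge list,
#' topology and disruption TSVs, module membership, context reports) plus a
#' machine-readable manifest with the package version, seeds and a
#' parameter hash.  A stage failure aborts with the stage name; artifacts
#' written before the failure are preserved.
#'
#' @param config see \code{\link{normalize_pipeline_config}}.
#' @return the fitted \code{ncbroker}, invisibly, with attribute
#'   \code{outdir}.
#' @export
run_pipeline <- function(config) {
  cfg <- normalize_pipeline_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- stage_seed(cfg$seed, "simulate")
    sim <- run_stage("simulate", simulate_expression(do.call(sim_config, sim_args)))
    write_simulation(sim, file.path(outdir, "input"))
    x <- sim$expr
  } else if (!is.null(cfg$input)) {
    x <- run_stage("read", read_expression_tsv(cfg$input$matrix, cfg$input$meta,
                                               cfg$input$biotype))
  } else {
    stop("configuration error: config needs an 'input' or 'simulate' block")
  }

  control <- do.call(ncbroker_control, cfg$params)
  fit <- ncbroker(x, control = control, seed = cfg$seed)

  write_expression_tsv(fit$expr, outdir, prefix = "normalized")
  utils::write.table(fit$de, file.path(outdir, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_biclusters_json(fit$biclusters, file.path(outdir, "biclusters.json"))
  utils::write.table(cbind(bicluster = rownames(fit$fractions),
                           as.data.frame(fit$fractions)),
                     file.path(outdir, "subtype_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$selection, file.path(outdir, "signature_biclusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network_graphml(fit$network, file.path(outdir, "template_network.graphml"))
  write_edge_list_tsv(fit$network, file.path(outdir, "template_network_edges.tsv"))
  utils::write.table(fit$topology, file.path(outdir, "topology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fit$disruption)) {
    utils::write.table(as.data.frame(fit$disruption),
                       file.path(outdir, "disruption.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_landscape(fit$landscape, outdir)
  render_report(fit$contexts, "tsv", file.path(outdir, "broker_contexts.tsv"))
  render_report(fit$contexts, "json", file.path(outdir, "broker_contexts.json"))
  render_report(fit$contexts, "markdown", file.path(outdir, "broker_contexts.md"))

  manifest <- list(
    package = "ncbroker",
    version = as.character(utils::packageVersion("ncbroker")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    stage_seeds = stats::setNames(
      lapply(c("simulate", "isa", "robustness", "network", "disrupt"),
             function(s) stage_seed(cfg$seed, s)),
      c("simulate", "isa", "robustness", "network", "disrupt")),
    parameter_hash = config_hash(cfg$params),
    params = cfg$params
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(fit, "outdir") <- outdir
  invisible(fit)
}
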