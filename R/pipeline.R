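# End-to-end analysis object and the config-driven pipeline driver.

#' Full PPI network functional-organization analysis
#'
#' Runs the complete analysis on a network with temporal group labels and
#' functional annotations: per-group topology (degree, clustering,
#' network distances, interaction density, rates of change, Erdos-Renyi
#' comparison), the functional distance space (sub-root annotation
#' matrix, Mahalanobis distances, group dendrogram with permutation test,
#' distance-vs-age and distance-vs-network-distance correlations), the
#' hub-neighborhood coherence test against degree-preserving nulls with
#' its bias controls, term enrichment, and per-group omega summaries.
#'
#' @param net a \code{\link{ppi_network}}.
#' @param groups named integer vector of temporal groups (1 = oldest).
#' @param ages_mya group ages in Mya, strictly decreasing.
#' @param annotations named list gene -> term IDs (omit to skip all
#'   function-based stages).
#' @param obo an \code{obo_ontology} matching \code{annotations}.
#' @param namespace annotation namespace.
#' @param omega optional named omega (Ka/Ks) vector.
#' @param dup_clusters optional \code{duplication_clusters} used for the
#'   duplication bias control of the hub analysis.
#' @param hub_min_degree minimum hub degree, or \code{NULL} to use the
#'   0.98 degree quantile.
#' @param dendro_reps,er_reps,rewire_reps replicate counts for the three
#'   resampling tests.
#' @param seed RNG seed governing every stochastic stage.
#' @return object of class \code{ppin_analysis}; see the methods
#'   \code{print}, \code{summary} and \code{plot}.
#' @export
ppin_analysis <- function(net, groups, ages_mya,
                          annotations = NULL, obo = NULL,
                          namespace = "biological_process",
                          omega = NULL, dup_clusters = NULL,
                          hub_min_degree = NULL,
                          dendro_reps = 200, er_reps = 200,
                          rewire_reps = 10, seed = 1) {
  set.seed(seed)
  groups <- groups[intersect(names(groups), network_nodes(net))]
  res <- list(seed = seed, n_nodes = net$n_nodes, n_edges = net$n_edges)
  res$topology <- topology_summary(net, groups, ages_mya)
  dist <- all_pairs_distances(net)
  res$group_distance <- group_distance_matrix(net, groups, dist = dist)
  res$density <- interaction_density(net, groups, normalize = TRUE)
  res$degree_distribution <- degree_histogram_loglog(net)
  res$er_test <- er_clustering_test(net, reps = er_reps)
  summ <- res$topology$summary
  res$rates <- list(
    degree = rate_of_change(summ$mean_degree, ages_mya),
    clustering = rate_of_change(summ$mean_clustering, ages_mya),
    network_distance = rate_of_change(
      unname(attr(res$group_distance, "per_group_mean")), ages_mya))
  if (!is.null(omega))
    res$omega <- omega_by_group(omega, groups)
  if (!is.null(annotations)) {
    if (is.null(obo)) stop("annotations supplied without an ontology")
    am <- build_annotation_matrix(annotations, obo, namespace)
    res$annotation_matrix <- am
    fd <- pairwise_functional_distances(am, genes = names(groups))
    res$tg_functional <- tg_functional_matrix(fd, groups)
    res$dendrogram <- dendrogram_with_permutation(fd, groups,
                                                  reps = dendro_reps)
    res$funcdist_age <- corr_funcdist_vs_agediff(res$tg_functional)
    res$funcdist_netdist <- funcdist_by_network_distance(fd, dist)
    deg <- network_degree(net)[names(groups)]
    hmd <- if (is.null(hub_min_degree)) {
      max(2, ceiling(quantile(deg, 0.98)))
    } else hub_min_degree
    try_hub <- function(...) {
      tryCatch(suppressWarnings(hub_null_comparison(
        net, groups, fd, hub_min_degree = hmd, reps = rewire_reps, ...)),
        error = function(e) {
          message("hub analysis skipped: ", conditionMessage(e))
          NULL
        })
    }
    res$hub <- try_hub()
    res$hub_no_interacting <- try_hub(exclude_interacting = TRUE)
    if (!is.null(dup_clusters))
      res$hub_no_duplicates <- try_hub(exclude_dup_clusters = dup_clusters)
    if (!is.null(res$hub))
      res$distance2 <- distance2_baseline(fd, dist,
                                          res$hub$empirical$per_hub)
    categories <- lapply(setNames(colnames(am$X), colnames(am$X)),
                         function(t) rownames(am$X)[am$X[, t] > 0])
    cc <- clustering_coefficient(net, names(groups))
    res$controlled <- list(
      degree = try_controlled(deg, groups, categories),
      clustering = try_controlled(cc, groups, categories),
      network_distance = try_controlled(
        node_mean_distance(dist, names(groups)), groups, categories))
    res$enrichment <- group_term_enrichment(groups, am)
    res$zscore_degree <- property_zscore_enrichment(deg, categories)
  }
  class(res) <- "ppin_analysis"
  res
}

try_controlled <- function(property, groups, categories) {
  tryCatch(controlled_correlation(property, groups, categories),
           error = function(e) NULL)
}

node_mean_distance <- function(dist, ids) {
  d <- dist[ids, ids]
  d[!is.finite(d)] <- NA
  diag(d) <- NA
  rowMeans(d, na.rm = TRUE)
}

#' @export
print.ppin_analysis <- function(x, ...) {
  cat("PPI network functional-organization analysis\n")
  cat("  network:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  cat(sprintf("  degree by group: KW H = %.2f, p = %.3g; degree vs age rank rho = %.3f\n",
              x$topology$degree_kw$H, x$topology$degree_kw$p,
              x$topology$degree_age_spearman$rho))
  cat(sprintf("  clustering vs Erdos-Renyi null: observed %.3f, p = %.3g\n",
              x$er_test$observed, x$er_test$p))
  if (!is.null(x$dendrogram))
    cat(sprintf("  group dendrogram permutation p = %.3g; funcdist vs age rho = %.3f\n",
                x$dendrogram$p, x$funcdist_age$rho))
  if (!is.null(x$hub))
    cat(sprintf("  hub coherence vs rewired nulls: H = %.2f (df = 1), p = %.3g, direction %+d\n",
                x$hub$H, x$hub$p, x$hub$direction))
  if (!is.null(x$distance2))
    cat(sprintf("  hub pairs vs distance-2 baseline: Z = %.2f, p = %.3g\n",
                x$distance2$z, x$distance2$p))
  invisible(x)
}

#' @export
summary.ppin_analysis <- function(object, ...) {
  print(object)
  cat("\nPer-group topology:\n")
  print(object$topology$summary, row.names = FALSE)
  if (!is.null(object$omega)) {
    cat(sprintf("\nOmega by group (KW H = %.2f, p = %.3g):\n",
                object$omega$H, object$omega$p))
    print(object$omega$summary, row.names = FALSE)
  }
  if (!is.null(object$tg_functional)) {
    cat("\nGroup functional distances:\n")
    print(object$tg_functional)
  }
  if (!is.null(object$enrichment)) {
    cat("\n")
    print(object$enrichment)
  }
  invisible(object)
}

#' @export
plot.ppin_analysis <- function(x, which = c("degree", "dendrogram"), ...) {
  which <- match.arg(which)
  if (which == "degree") {
    tab <- x$degree_distribution$table
    tab <- tab[tab$p_k > 0, ]
    plot(tab$k, tab$p_k, log = "xy", xlab = "degree k", ylab = "P(k)",
         main = "Degree distribution (log-log)", pch = 19, ...)
  } else {
    if (is.null(x$dendrogram)) stop("no dendrogram in this analysis")
    plot(x$dendrogram$tree,
         main = sprintf("Temporal group dendrogram (p = %.3g)",
                        x$dendrogram$p),
         xlab = "", sub = "")
  }
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Drives the analysis end to end from a YAML file or config list and
#' writes a directory of plain-text results: per-group summary tables,
#' the network/functional group matrices, density matrices, rate tables,
#' enrichment tables, the dendrogram in Newick, the functional profile
#' over network distance, and a JSON manifest recording every parameter,
#' seed and filtering count. Re-running with the same config and seed
#' reproduces all outputs.
#'
#' The config either contains a \code{simulate} block (arguments for
#' \code{\link{generator_config}}) or an \code{inputs} block with paths
#' \code{net}, \code{groups} (or \code{hits} + scheme options),
#' \code{gaf}, \code{obo}, and optionally \code{omega} and
#' \code{self_hits}.
#'
#' @param config path to a YAML file, or a config list.
#' @param out_dir output directory.
#' @return invisibly, the \code{ppin_analysis} object.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (!is.null(config$seed)) config$seed else 1
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, config = config,
                   r_version = as.character(getRversion()))
  if (!is.null(config$simulate)) {
    gc_args <- config$simulate
    gc_args$seed <- seed
    study <- simulate_ppi_study(do.call(generator_config, gc_args))
    net <- study$net; groups <- study$groups; ages <- study$ages_mya
    annotations <- study$annotations; obo <- study$obo
    omega <- study$omega
    dup <- build_duplication_clusters(study$self_hits,
                                      threshold = study$config$dup_threshold,
                                      genes = network_nodes(net))
    manifest$simulated <- list(n_nodes = net$n_nodes, n_edges = net$n_edges,
                               n_dropped = study$truth$n_dropped)
  } else if (!is.null(config$inputs)) {
    ins <- config$inputs
    if (is.null(ins$net)) stop("missing stage input: net")
    net <- read_edge_list(ins$net,
                          format = if (is.null(ins$format)) "tsv" else ins$format)
    scheme <- temporal_group_scheme()
    if (!is.null(ins$groups)) {
      groups <- read_groups(ins$groups)
    } else if (!is.null(ins$hits)) {
      groups <- assign_temporal_groups(read_hit_table(ins$hits), scheme,
                                       genes = network_nodes(net))
    } else stop("missing stage input: groups or hits")
    ages <- if (!is.null(config$ages_mya)) config$ages_mya else scheme$ages_mya
    annotations <- obo <- NULL
    if (!is.null(ins$gaf)) {
      if (is.null(ins$obo)) stop("missing stage input: obo (needed with gaf)")
      obo <- read_obo(ins$obo)
      annotations <- read_annotations(ins$gaf, obo)
    }
    omega <- if (!is.null(ins$omega)) read_omega_table(ins$omega) else NULL
    dup <- if (!is.null(ins$self_hits)) {
      build_duplication_clusters(read_hit_table(ins$self_hits),
                                 genes = network_nodes(net))
    } else NULL
  } else stop("config needs a 'simulate' or 'inputs' block")
  skip_fun <- isTRUE(config$skip_funcdist)
  an <- ppin_analysis(
    net, groups, ages,
    annotations = if (skip_fun) NULL else annotations,
    obo = obo, omega = omega, dup_clusters = dup,
    hub_min_degree = config$hub_min_degree,
    dendro_reps = config$dendro_reps %||% 200,
    er_reps = config$er_reps %||% 200,
    rewire_reps = config$rewire_reps %||% 10,
    seed = seed)
  p <- function(f) file.path(out_dir, f)
  wt <- function(df, f) write.table(df, p(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  wt(an$topology$summary, "tg_summary.tsv")
  write_group_matrix(an$group_distance, p("network_distance_matrix.tsv"))
  wt(as.data.frame(an$density$D), "interaction_density.tsv")
  if (!is.null(an$density$D_normalized))
    wt(as.data.frame(an$density$D_normalized),
       "interaction_density_normalized.tsv")
  rates <- do.call(rbind, lapply(names(an$rates), function(nm)
    cbind(property = nm, an$rates[[nm]])))
  wt(rates, "rate_of_change.tsv")
  if (!is.null(an$omega)) wt(an$omega$summary, "omega_by_group.tsv")
  if (!is.null(an$tg_functional)) {
    write_group_matrix(an$tg_functional, p("functional_distance_matrix.tsv"))
    write_newick(an$dendrogram$tree, p("tg_dendrogram.nwk"))
    wt(an$funcdist_netdist$profile, "funcdist_by_network_distance.tsv")
    wt(an$enrichment$table, "enrichment.tsv")
    wt(an$enrichment$summary, "enrichment_summary.tsv")
    manifest$function_stage <- list(
      dendrogram_p = an$dendrogram$p,
      funcdist_age_rho = an$funcdist_age$rho,
      funcdist_netdist_rho = an$funcdist_netdist$rho,
      genes_without_subroot = length(an$annotation_matrix$zero_rows))
    if (!is.null(an$hub))
      manifest$hub_stage <- list(
        hub_min_degree = an$hub$empirical$hub_min_degree,
        n_hubs = an$hub$empirical$n_hubs,
        n_skipped_hubs = an$hub$empirical$n_skipped_hubs,
        H = an$hub$H, p = an$hub$p, direction = an$hub$direction,
        distance2_z = an$distance2$z)
  }
  manifest$topology_stage <- list(
    n_nodes = an$n_nodes, n_edges = an$n_edges,
    cleaning_log = net$cleaning_log,
    degree_kw_H = an$topology$degree_kw$H,
    degree_age_rho = an$topology$degree_age_spearman$rho,
    er_p = an$er_test$p)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(an)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
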