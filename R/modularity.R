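# Hub-neighborhood functional coherence against degree-preserving null
# networks, with bias controls; controlled correlations; enrichment
# statistics.

#' Degree-preserving rewiring by double edge swaps
#'
#' Randomizes interaction partners while keeping every node's degree
#' exactly fixed, by repeated double-edge swaps that reject self-loops and
#' multi-edges.
#'
#' @param net a \code{\link{ppi_network}}.
#' @param n_swaps_per_edge attempted swaps per edge (default 10).
#' @param seed optional RNG seed.
#' @return a rewired \code{\link{ppi_network}} with the same degree
#'   sequence. For graphs too constrained to swap (e.g. complete graphs)
#'   the input is returned, with a warning.
#' @export
rewire_degree_preserving <- function(net, n_swaps_per_edge = 10, seed = NULL) {
  stopifnot(n_swaps_per_edge > 0)
  if (!is.null(seed)) set.seed(seed)
  niter <- max(1L, round(n_swaps_per_edge * net$n_edges))
  g <- igraph::rewire(net$graph,
                      igraph::keeping_degseq(loops = FALSE, niter = niter))
  deg0 <- igraph::degree(net$graph)
  deg1 <- igraph::degree(g)[names(deg0)]
  if (!identical(unname(deg0), unname(deg1)))
    stop("internal error: rewiring changed the degree sequence")
  overlap <- edge_overlap(net$graph, g)
  if (overlap > 0.99 && net$n_edges > 3)
    warning("graph too constrained to rewire; returning near-identical graph")
  out <- list(graph = g, n_nodes = igraph::vcount(g),
              n_edges = igraph::ecount(g),
              cleaning_log = list(self_loops = 0L, duplicates = 0L))
  class(out) <- "ppi_network"
  attr(out, "edge_overlap") <- overlap
  out
}

edge_overlap <- function(g1, g2) {
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  length(intersect(key(g1), key(g2))) / igraph::ecount(g1)
}

#' Per-hub group distance: functional coherence of hub neighborhoods
#'
#' A topological unit is a hub (node with degree at least
#' \code{hub_min_degree}) plus all its interaction partners. For each hub
#' the group distance is the mean functional distance over unordered
#' partner pairs drawn from \emph{different} temporal groups — restricting
#' to cross-group pairs controls the temporal effect (same-group genes are
#' functionally close regardless of the hub). Two bias controls are
#' available: dropping partner pairs that themselves interact
#' (\code{exclude_interacting}), and removing all genes with duplication
#' evidence before the analysis (\code{exclude_dup_clusters}).
#'
#' @param net a \code{\link{ppi_network}}.
#' @param groups named integer vector of temporal groups.
#' @param funcdist pairwise functional distance matrix.
#' @param hub_min_degree minimum hub degree (default 50).
#' @param exclude_interacting drop partner pairs that are edges.
#' @param exclude_dup_clusters optional \code{duplication_clusters}; genes
#'   in multi-gene clusters are removed from the network first (degrees
#'   and hub status are recomputed after removal).
#' @return object of class \code{hub_analysis}: list with
#'   \code{per_hub} (named numeric vector of group distances),
#'   \code{pair_values} (pooled functional distances over all qualifying
#'   pairs), \code{n_hubs}, \code{n_skipped_hubs},
#'   \code{n_skipped_pairs} (missing functional distance) and the
#'   parameters used.
#' @export
hub_group_distance <- function(net, groups, funcdist, hub_min_degree = 50,
                               exclude_interacting = FALSE,
                               exclude_dup_clusters = NULL) {
  stopifnot(hub_min_degree >= 2)
  if (!is.null(exclude_dup_clusters)) {
    drop <- duplicated_genes(exclude_dup_clusters)
    net <- induced_network(net, setdiff(network_nodes(net), drop))
  }
  deg <- network_degree(net)
  hubs <- names(deg)[deg >= hub_min_degree]
  per_hub <- numeric(0)
  pair_values <- numeric(0)
  n_skipped_hubs <- 0L
  n_skipped_pairs <- 0L
  g <- net$graph
  for (h in hubs) {
    partners <- igraph::as_ids(igraph::neighbors(g, h))
    partners <- partners[partners %in% names(groups) &
                           partners %in% rownames(funcdist)]
    if (length(partners) < 2L) { n_skipped_hubs <- n_skipped_hubs + 1L; next }
    pg <- groups[partners]
    pairs <- utils::combn(seq_along(partners), 2L)
    diffg <- pg[pairs[1L, ]] != pg[pairs[2L, ]]
    pairs <- pairs[, diffg, drop = FALSE]
    if (exclude_interacting && ncol(pairs)) {
      vp <- as.vector(t(cbind(partners[pairs[1L, ]], partners[pairs[2L, ]])))
      is_edge <- igraph::get_edge_ids(g, vp, error = FALSE) > 0
      pairs <- pairs[, !is_edge, drop = FALSE]
    }
    if (!ncol(pairs)) { n_skipped_hubs <- n_skipped_hubs + 1L; next }
    vals <- funcdist[cbind(partners[pairs[1L, ]], partners[pairs[2L, ]])]
    bad <- !is.finite(vals)
    n_skipped_pairs <- n_skipped_pairs + sum(bad)
    vals <- vals[!bad]
    if (!length(vals)) { n_skipped_hubs <- n_skipped_hubs + 1L; next }
    per_hub[h] <- mean(vals)
    pair_values <- c(pair_values, vals)
  }
  if (length(per_hub) < 5L)
    warning("fewer than 5 hubs with qualifying pairs (", length(per_hub), ")")
  structure(list(per_hub = per_hub, pair_values = pair_values,
                 n_hubs = length(per_hub), n_skipped_hubs = n_skipped_hubs,
                 n_skipped_pairs = n_skipped_pairs,
                 hub_min_degree = hub_min_degree,
                 exclude_interacting = exclude_interacting,
                 excluded_duplicates = !is.null(exclude_dup_clusters)),
            class = "hub_analysis")
}

#' @export
print.hub_analysis <- function(x, ...) {
  cat("Hub group-distance analysis: ", x$n_hubs, " hubs (min degree ",
      x$hub_min_degree, "), mean group distance ",
      format(mean(x$per_hub), digits = 4), "\n", sep = "")
  if (x$exclude_interacting) cat("  interacting partner pairs excluded\n")
  if (x$excluded_duplicates) cat("  duplication-cluster genes excluded\n")
  invisible(x)
}

#' Compare hub group distances against rewired null networks
#'
#' Rebuilds the hub analysis on \code{reps} degree-preserving rewirings of
#' the network (functional annotations and temporal groups stay attached
#' to the genes; only the interaction partners are shuffled), pools the
#' per-hub group distances from all rewirings, and compares empirical vs
#' null values with a two-sample Kruskal-Wallis test (equivalent to
#' Mann-Whitney; df = 1).
#'
#' @inheritParams hub_group_distance
#' @param reps number of rewired networks (default 20).
#' @param seed optional RNG seed.
#' @param n_swaps_per_edge swaps per edge for each rewiring.
#' @param pool \code{"values"} pools per-hub values from all reps (the
#'   default); \code{"rep_means"} uses one mean per rep.
#' @return list with \code{empirical} (a \code{hub_analysis}),
#'   \code{null_values}, \code{H}, \code{df}, \code{p},
#'   \code{direction} (sign of empirical mean minus null mean) and
#'   \code{reps}.
#' @export
hub_null_comparison <- function(net, groups, funcdist, hub_min_degree = 50,
                                exclude_interacting = FALSE,
                                exclude_dup_clusters = NULL,
                                reps = 20, seed = NULL,
                                n_swaps_per_edge = 10,
                                pool = c("values", "rep_means")) {
  pool <- match.arg(pool)
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  emp <- hub_group_distance(net, groups, funcdist, hub_min_degree,
                            exclude_interacting, exclude_dup_clusters)
  if (!length(emp$per_hub))
    stop("no hubs with qualifying partner pairs at min degree ",
         hub_min_degree)
  null_values <- unlist(lapply(seq_len(reps), function(i) {
    rw <- rewire_degree_preserving(net, n_swaps_per_edge)
    ha <- suppressWarnings(
      hub_group_distance(rw, groups, funcdist, hub_min_degree,
                         exclude_interacting, exclude_dup_clusters))
    if (pool == "values") ha$per_hub else mean(ha$per_hub)
  }), use.names = FALSE)
  null_values <- null_values[is.finite(null_values)]
  if (!length(null_values)) stop("no null hub values; network too small?")
  kw <- kruskal.test(list(emp$per_hub, null_values))
  list(empirical = emp, null_values = null_values,
       H = unname(kw$statistic), df = unname(kw$parameter), p = kw$p.value,
       direction = sign(mean(emp$per_hub) - mean(null_values)), reps = reps)
}

#' Z comparison of hub partner pairs against the distance-2 baseline
#'
#' Non-interacting partners of a hub sit at network distance two, so the
#' natural baseline for hub-pair functional distances is the overall
#' functional distance of all gene pairs at network distance two.
#' Z = (mean of hub values - mean of distance-2 pairs) / SE of the
#' difference, with a two-sided Gaussian p-value; negative Z means hub
#' partner pairs are functionally closer than the baseline. Pass the
#' per-hub group distances (\code{per_hub} from
#' \code{\link{hub_group_distance}}) as the empirical side: partner pairs
#' of one hub share genes and are correlated, so the hub mean is the
#' independent sampling unit and keeps the Z calibrated.
#'
#' @param funcdist pairwise functional distance matrix.
#' @param netdist pairwise network distance matrix.
#' @param hub_values empirical-side values, one per sampling unit
#'   (typically per-hub group distances).
#' @param max_d2_pairs optional cap on the number of distance-2 pairs
#'   (seeded subsample; size logged in the result).
#' @param seed RNG seed for subsampling.
#' @return list with \code{z}, \code{p}, means and sample sizes of both
#'   sides.
#' @export
distance2_baseline <- function(funcdist, netdist, hub_values,
                               max_d2_pairs = NULL, seed = NULL) {
  ids <- intersect(rownames(funcdist), rownames(netdist))
  fd <- funcdist[ids, ids]; nd <- netdist[ids, ids]
  sel <- upper.tri(nd) & nd == 2 & is.finite(fd)
  d2 <- fd[sel]
  if (!is.null(max_d2_pairs) && max_d2_pairs < length(d2)) {
    if (!is.null(seed)) set.seed(seed)
    d2 <- d2[sample.int(length(d2), max_d2_pairs)]
  }
  x <- hub_values
  if (length(x) < 2L || length(d2) < 2L)
    stop("need at least 2 values on each side")
  se <- sqrt(var(x) / length(x) + var(d2) / length(d2))
  z <- (mean(x) - mean(d2)) / se
  list(z = z, p = 2 * pnorm(-abs(z)),
       mean_hub = mean(x), n_hub = length(x),
       mean_d2_pairs = mean(d2), n_d2_pairs = length(d2))
}

#' Correlation of a node property with gene age, controlling for function
#'
#' Compares the global Spearman correlation between a per-node property
#' (degree, clustering coefficient, mean network distance, ...) and the
#' temporal group index with the correlations computed within each
#' functional category separately. The controlled coefficient is the
#' unweighted mean of the per-category coefficients; a one-sample t-test
#' of the per-category coefficients against the global value asks whether
#' controlling for function changed the correlation (df = number of
#' retained categories - 1).
#'
#' @param property named numeric vector of the node property.
#' @param groups named integer vector of temporal groups.
#' @param categories named list: functional category (e.g. sub-root term)
#'   to gene ID vector.
#' @param min_genes minimum usable genes per category (default 10).
#' @param weighted use a size-weighted mean of per-category coefficients
#'   instead of the unweighted mean.
#' @return list with \code{global_rho}, \code{controlled_rho},
#'   \code{per_category} data frame, \code{t}, \code{df}, \code{p},
#'   \code{n_excluded}.
#' @export
controlled_correlation <- function(property, groups, categories,
                                   min_genes = 10, weighted = FALSE) {
  ids <- intersect(names(property), names(groups))
  ids <- ids[is.finite(property[ids])]
  glob <- suppressWarnings(
    cor(property[ids], groups[ids], method = "spearman"))
  rows <- lapply(names(categories), function(ct) {
    gs <- intersect(categories[[ct]], ids)
    if (length(gs) < min_genes) return(NULL)
    p <- property[gs]; g <- groups[gs]
    if (length(unique(p)) < 2L || length(unique(g)) < 2L) return(NULL)
    data.frame(category = ct, n = length(gs),
               rho = suppressWarnings(cor(p, g, method = "spearman")),
               stringsAsFactors = FALSE)
  })
  per_cat <- do.call(rbind, rows)
  if (is.null(per_cat) || nrow(per_cat) < 2L)
    stop("need at least 2 categories with >= ", min_genes, " usable genes")
  ctrl <- if (weighted) {
    sum(per_cat$rho * per_cat$n) / sum(per_cat$n)
  } else mean(per_cat$rho)
  tt <- t.test(per_cat$rho, mu = glob)
  list(global_rho = glob, controlled_rho = ctrl, per_category = per_cat,
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       n_excluded = length(categories) - nrow(per_cat))
}

#' Hypergeometric term enrichment per temporal group
#'
#' For each (group, sub-root term) pair, tests over-representation of the
#' term among the group's genes against a background (network genes by
#' default) with the hypergeometric upper tail. P-values are BH-corrected
#' within each group's family. "Unique" significant terms are significant
#' in exactly one group.
#'
#' @param groups named integer vector of temporal groups.
#' @param am an \code{\link{annotation_matrix}}.
#' @param background gene IDs forming the background universe (default:
#'   all genes with a group that appear in the annotation matrix).
#' @param alpha significance level on the BH q-value (default 0.05).
#' @return object of class \code{enrichment_table}: list with
#'   \code{table} (data frame: group, term, count_in_group,
#'   count_in_background, n_group, n_background, p, q, significant) and
#'   \code{summary} (data frame: group, significant_terms, unique_terms).
#' @export
group_term_enrichment <- function(groups, am, background = NULL,
                                  alpha = 0.05) {
  if (is.null(background))
    background <- intersect(names(groups), rownames(am$X))
  background <- intersect(background, rownames(am$X))
  groups <- groups[intersect(names(groups), background)]
  if (!all(names(groups) %in% background)) stop("background must contain every group gene")
  X <- am$X[background, , drop = FALSE]
  N <- length(background)
  term_tot <- colSums(X)
  lev <- sort(unique(groups))
  rows <- list()
  for (g in lev) {
    members <- names(groups)[groups == g]
    n_g <- length(members)
    cnt <- colSums(X[members, , drop = FALSE])
    p <- phyper(cnt - 1, term_tot, N - term_tot, n_g, lower.tail = FALSE)
    keep <- term_tot > 0
    q <- p.adjust(p[keep], method = "BH")
    rows[[as.character(g)]] <- data.frame(
      group = g, term = colnames(X)[keep],
      count_in_group = as.integer(cnt[keep]),
      count_in_background = as.integer(term_tot[keep]),
      n_group = n_g, n_background = N,
      p = as.numeric(p[keep]), q = as.numeric(q),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$significant <- tab$q <= alpha
  sig_groups <- table(tab$term[tab$significant])
  summ <- data.frame(
    group = lev,
    significant_terms = vapply(lev, function(g)
      sum(tab$significant & tab$group == g), 0L),
    unique_terms = vapply(lev, function(g) {
      sig_terms_g <- tab$term[tab$significant & tab$group == g]
      sum(sig_groups[sig_terms_g] == 1L)
    }, 0L))
  structure(list(table = tab, summary = summ, alpha = alpha),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("Term enrichment (hypergeometric, BH within group, alpha =",
      x$alpha, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Z-score enrichment of a node property within functional categories
#'
#' z = (category mean - overall mean) / (overall SD / sqrt(category
#' size)); significance from the Gaussian distribution, two-sided, with BH
#' correction across categories.
#'
#' @param property named numeric vector.
#' @param categories named list: category to gene IDs.
#' @return data frame with columns category, n, mean, z, p, q.
#' @export
property_zscore_enrichment <- function(property, categories) {
  property <- property[is.finite(property)]
  mu <- mean(property); s <- sd(property)
  if (!is.finite(s) || s == 0) stop("zero overall variance in property")
  rows <- lapply(names(categories), function(ct) {
    gs <- intersect(categories[[ct]], names(property))
    if (length(gs) < 2L) return(NULL)
    z <- (mean(property[gs]) - mu) / (s / sqrt(length(gs)))
    data.frame(category = ct, n = length(gs), mean = mean(property[gs]),
               z = z, p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no category with >= 2 genes")
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
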