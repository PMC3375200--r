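# Graph statistics: local clustering, shortest paths, per-group summaries,
# interaction density, rates of change, Erdos-Renyi comparison, log-log
# degree distribution.

#' Local clustering coefficient
#'
#' Fraction of a node's neighbor pairs that are themselves connected:
#' 2T / (k (k - 1)) where T is the number of triangles through the node.
#' Undefined (\code{NA}) for nodes with degree below 2.
#'
#' @param net a \code{\link{ppi_network}}.
#' @param nodes node IDs (default: all nodes).
#' @return named numeric vector in \code{[0, 1]} with \code{NA} where
#'   undefined.
#' @export
clustering_coefficient <- function(net, nodes = network_nodes(net)) {
  missing_nodes <- setdiff(nodes, network_nodes(net))
  if (length(missing_nodes))
    stop("unknown node: ", missing_nodes[1L])
  cc <- igraph::transitivity(net$graph, type = "local", vids = nodes,
                             isolates = "NaN")
  cc[is.nan(cc)] <- NA_real_
  setNames(cc, nodes)
}

#' All-pairs shortest-path (network) distances
#'
#' Breadth-first search from every node on the unweighted graph.
#' Unreachable pairs are \code{Inf}; they are excluded from any averaging
#' done downstream.
#'
#' @param net a \code{\link{ppi_network}}.
#' @return symmetric numeric matrix of hop counts with node ID dimnames;
#'   diagonal 0, unreachable pairs \code{Inf}.
#' @export
all_pairs_distances <- function(net) {
  igraph::distances(net$graph, algorithm = "unweighted")
}

#' Per-group average network distances
#'
#' Averages shortest-path distances over gene pairs grouped by temporal
#' group combination. Within-group pairs are counted once; unreachable
#' pairs are excluded from the mean but reflected in the per-cell coverage
#' fraction (attribute \code{"coverage"}). The per-group mean distance to
#' all other proteins (attribute \code{"per_group_mean"}) is the
#' pair-count-weighted mean over that group's row.
#'
#' @param net a \code{\link{ppi_network}}.
#' @param groups named integer vector of temporal groups.
#' @param dist optional precomputed \code{\link{all_pairs_distances}}
#'   matrix.
#' @return a \code{\link{group_matrix}} of kind \code{network_distance}.
#' @export
group_distance_matrix <- function(net, groups, dist = NULL) {
  if (is.null(dist)) dist <- all_pairs_distances(net)
  gm <- group_pair_means(dist, groups, kind = "network_distance")
  attr(gm, "per_group_mean") <- group_row_weighted_mean(gm)
  gm
}

#' Pair-count-weighted row means of a group matrix
#'
#' For each group, the weighted mean of its row cells with weights equal to
#' the number of pairs contributing to each cell; for network distance this
#' is the group's average distance to all (reachable) proteins.
#'
#' @param gm a \code{\link{group_matrix}}.
#' @param weights optional matrix of weights overriding
#'   \code{gm$pair_counts} (e.g. population pair counts).
#' @return named numeric vector, one value per group.
#' @export
group_row_weighted_mean <- function(gm, weights = NULL) {
  w <- if (is.null(weights)) gm$pair_counts else weights
  vals <- gm$values
  out <- vapply(seq_len(nrow(vals)), function(m) {
    ok <- !is.na(vals[m, ]) & w[m, ] > 0
    sum(vals[m, ok] * w[m, ok]) / sum(w[m, ok])
  }, 0)
  setNames(out, rownames(vals))
}

#' Interaction density between temporal groups
#'
#' D[m, n] = I[m, n] / E[m, n], where I counts observed edges between
#' groups m and n and E the possible pairs: N_m N_n for distinct groups and
#' N_m (N_m - 1) / 2 within a group. With \code{normalize = TRUE} each row
#' m is divided by that group's overall density
#' (sum_n I[m, n]) / (sum_n E[m, n]), making rows comparable; with
#' \code{normalize = "network"} all cells are divided by the whole-network
#' density instead.
#'
#' @param net a \code{\link{ppi_network}}; every node must have a group.
#' @param groups named integer vector of temporal groups.
#' @param normalize \code{FALSE}, \code{TRUE} (row-wise) or
#'   \code{"network"}.
#' @return object of class \code{interaction_density}: list with matrices
#'   \code{I}, \code{E}, \code{D}, optional \code{D_normalized}, group
#'   sizes \code{N} and the normalization used. Cells with E = 0 are
#'   \code{NA}.
#' @export
interaction_density <- function(net, groups, normalize = FALSE) {
  ids <- network_nodes(net)
  if (!all(ids %in% names(groups)))
    stop("every network node needs a temporal group; missing: ",
         setdiff(ids, names(groups))[1L])
  grp <- groups[ids]
  lev <- sort(unique(grp))
  k <- length(lev)
  N <- as.integer(table(factor(grp, levels = lev)))
  el <- network_edges(net)
  gi <- match(grp[el[, 1L]], lev)
  gj <- match(grp[el[, 2L]], lev)
  I <- matrix(0, k, k)
  for (e in seq_along(gi)) {
    m <- min(gi[e], gj[e]); n <- max(gi[e], gj[e])
    I[m, n] <- I[m, n] + 1
  }
  I <- I + t(I) - diag(diag(I))
  E <- outer(N, N)
  diag(E) <- N * (N - 1) / 2
  D <- ifelse(E > 0, I / E, NA_real_)
  labs <- paste0("TG", lev)
  dimnames(I) <- dimnames(E) <- dimnames(D) <- list(labs, labs)
  out <- list(I = I, E = E, D = D, N = setNames(N, labs),
              normalize = normalize)
  if (!identical(normalize, FALSE)) {
    if (identical(normalize, "network")) {
      overall <- sum(I[upper.tri(I, diag = TRUE)]) /
        sum(E[upper.tri(E, diag = TRUE)])
      out$D_normalized <- D / overall
    } else {
      row_density <- rowSums(I) / rowSums(E)
      out$D_normalized <- sweep(D, 1L, row_density, "/")
    }
  }
  class(out) <- "interaction_density"
  out
}

#' @export
print.interaction_density <- function(x, digits = 4, ...) {
  cat("Interaction density over", length(x$N), "groups",
      if (!identical(x$normalize, FALSE)) "(normalized available)", "\n")
  print(signif(x$D, digits))
  invisible(x)
}

#' Rates of change of a network property between consecutive groups
#'
#' For each consecutive evolutionary stage (group i to i + 1) the rate is
#' the absolute property difference per million years,
#' |v[i+1] - v[i]| / (age[i] - age[i+1]). The last stage is excluded by
#' default (its age span is too short to estimate a rate reliably). Rates
#' are normalized across stages per property so different properties are
#' comparable.
#'
#' @param values numeric vector of the per-group property, oldest first.
#' @param ages_mya group ages in Mya, strictly decreasing.
#' @param normalize \code{"sum"} (divide by the sum over stages),
#'   \code{"max"} or \code{"none"}.
#' @param exclude_last drop the final stage (default \code{TRUE}).
#' @return data frame with columns \code{stage}, \code{rate},
#'   \code{rate_normalized}.
#' @export
rate_of_change <- function(values, ages_mya, normalize = c("sum", "max", "none"),
                           exclude_last = TRUE) {
  normalize <- match.arg(normalize)
  if (length(values) != length(ages_mya)) stop("values/ages length mismatch")
  if (length(values) < 2L) stop("need at least 2 consecutive groups")
  dt <- ages_mya[-length(ages_mya)] - ages_mya[-1L]
  if (any(dt == 0)) stop("equal consecutive ages")
  rate <- abs(diff(values)) / dt
  stage <- paste0("TG", seq_along(rate), "-TG", seq_along(rate) + 1L)
  if (exclude_last && length(rate) > 1L) {
    rate <- rate[-length(rate)]
    stage <- stage[-length(stage)]
  }
  denom <- switch(normalize, sum = sum(rate), max = max(rate), none = 1)
  norm <- if (denom > 0) rate / denom else rate
  data.frame(stage = stage, rate = rate, rate_normalized = norm,
             stringsAsFactors = FALSE)
}

#' Permutation comparison of clustering against Erdos-Renyi networks
#'
#' Draws \code{reps} Erdos-Renyi G(n, m) graphs with the same node and edge
#' counts as the observed network and compares mean local clustering
#' coefficients. The p-value uses the add-one rule
#' (1 + #\{null >= observed\}) / (reps + 1), so p is always in (0, 1].
#'
#' @param net a \code{\link{ppi_network}}.
#' @param reps number of null draws (default 1000).
#' @param seed optional RNG seed.
#' @return list with \code{observed}, \code{null} (numeric vector),
#'   \code{p} and \code{reps}.
#' @export
er_clustering_test <- function(net, reps = 1000, seed = NULL) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(clustering_coefficient(net), na.rm = TRUE)
  n <- net$n_nodes; m <- net$n_edges
  null <- vapply(seq_len(reps), function(i) {
    g <- igraph::sample_gnm(n, m)
    cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
    mean(cc[!is.nan(cc)], na.rm = TRUE)
  }, 0)
  p <- (1 + sum(null >= obs)) / (reps + 1)
  list(observed = obs, null = null, p = p, reps = reps)
}

#' Log-binned degree distribution and C(k) curve
#'
#' Bins degrees into logarithmic (base-2) bins, estimates the degree
#' distribution P(k) and the mean clustering coefficient per bin, and fits
#' a descriptive least-squares line to log10 P(k) vs log10 k. The slope is
#' a descriptive power-law summary, not a maximum-likelihood exponent.
#'
#' @param net a \code{\link{ppi_network}}.
#' @return list with \code{table} (data frame: k (bin geometric center),
#'   p_k, mean_c, n), \code{slope}, \code{r_squared}.
#' @export
degree_histogram_loglog <- function(net) {
  k <- network_degree(net)
  cc <- clustering_coefficient(net)
  kpos <- k[k > 0]
  edges_pow <- 2^(0:ceiling(log2(max(kpos) + 1)))
  bins <- findInterval(kpos, edges_pow)
  width <- diff(edges_pow)[sort(unique(bins))]
  centers <- sqrt(edges_pow[-length(edges_pow)] *
                  (edges_pow[-1L] - 1))[sort(unique(bins))]
  counts <- as.integer(table(bins))
  p_k <- counts / length(kpos) / width
  mean_c <- as.numeric(tapply(cc[k > 0], bins, mean, na.rm = TRUE))
  mean_c[is.nan(mean_c)] <- NA_real_
  tab <- data.frame(k = centers, p_k = p_k, mean_c = mean_c, n = counts)
  fit_tab <- tab[tab$p_k > 0, ]
  slope <- r2 <- NA_real_
  if (nrow(fit_tab) >= 2L) {
    fit <- lm(log10(p_k) ~ log10(k), data = fit_tab)
    slope <- unname(coef(fit)[2L])
    r2 <- summary(fit)$r.squared
  }
  list(table = tab, slope = slope, r_squared = r2)
}

#' Per-group topology summary
#'
#' Mean degree and mean clustering coefficient per temporal group (the
#' clustering mean is taken over nodes where it is defined, i.e. degree at
#' least 2), with Kruskal-Wallis tests across groups and the Spearman
#' correlation between degree and group index (group index serves as the
#' age rank: 6 tied levels, average-rank tie handling).
#'
#' @param net a \code{\link{ppi_network}}.
#' @param groups named integer vector of temporal groups.
#' @param ages_mya optional group ages attached to the summary table.
#' @return object of class \code{topology_summary}: list with
#'   \code{summary} data frame, Kruskal-Wallis results for degree and
#'   clustering, and \code{degree_age_spearman}.
#' @export
topology_summary <- function(net, groups, ages_mya = NULL) {
  ids <- intersect(network_nodes(net), names(groups))
  k <- network_degree(net)[ids]
  cc <- clustering_coefficient(net, ids)
  grp <- groups[ids]
  lev <- sort(unique(grp))
  f <- factor(grp, levels = lev)
  summ <- data.frame(
    group = lev,
    n = as.integer(table(f)),
    mean_degree = as.numeric(tapply(k, f, mean)),
    mean_clustering = as.numeric(tapply(cc, f, mean, na.rm = TRUE)))
  if (!is.null(ages_mya)) summ$age_mya <- ages_mya[seq_along(lev)]
  kw_deg <- kruskal.test(k, f)
  has_cc <- !is.na(cc)
  kw_cc <- kruskal.test(cc[has_cc], f[has_cc])
  rho <- suppressWarnings(
    cor.test(k, grp, method = "spearman", exact = FALSE))
  structure(list(summary = summ,
                 degree_kw = list(H = unname(kw_deg$statistic),
                                  df = unname(kw_deg$parameter),
                                  p = kw_deg$p.value),
                 clustering_kw = list(H = unname(kw_cc$statistic),
                                      df = unname(kw_cc$parameter),
                                      p = kw_cc$p.value),
                 degree_age_spearman = list(rho = unname(rho$estimate),
                                            p = rho$p.value)),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("Per-group topology summary\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("Degree KW: H = %.2f, df = %d, p = %.3g\n",
              x$degree_kw$H, x$degree_kw$df, x$degree_kw$p))
  cat(sprintf("Clustering KW: H = %.2f, df = %d, p = %.3g\n",
              x$clustering_kw$H, x$clustering_kw$df, x$clustering_kw$p))
  cat(sprintf("Degree vs age rank: Spearman rho = %.3f (p = %.3g)\n",
              x$degree_age_spearman$rho, x$degree_age_spearman$p))
  invisible(x)
}
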