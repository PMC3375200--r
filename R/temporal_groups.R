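# Phylostratigraphic temporal-group assignment, duplication clusters and
# per-group omega summaries.

#' Default clade-to-species scheme for six temporal groups
#'
#' Temporal group 1 (oldest) collects genes with a qualifying homolog in
#' protostome clades; groups 2-5 in fish, amphibians, birds and non-primate
#' mammals respectively; group 6 holds genes with no qualifying homolog in
#' any listed species (lineage-specific genes). Ages are approximate clade
#' divergence times in millions of years.
#'
#' @param evalue_threshold hit-qualification threshold; a hit counts when
#'   its e-value is less than or equal to this (default 1e-20).
#' @param ages_mya approximate group ages, strictly decreasing.
#' @return an object of class \code{temporal_group_scheme}: list with
#'   \code{clades} (ordered named list, group index to species vector),
#'   \code{ages_mya} and \code{evalue_threshold}.
#' @export
temporal_group_scheme <- function(evalue_threshold = 1e-20,
                                  ages_mya = c(990, 450, 360, 310, 90, 50)) {
  clades <- list(
    `1` = c("african_malaria_mosquito", "fruitfly", "nematode",
            "schistosoma", "yellow_fever_mosquito"),
    `2` = c("medaka", "pufferfish", "trout", "zebrafish"),
    `3` = c("clawed_frog", "tropical_frog"),
    `4` = c("chicken"),
    `5` = c("cattle", "dog", "pig", "sheep")
  )
  n_groups <- length(clades) + 1L
  if (length(ages_mya) != n_groups) stop("need one age per group")
  if (any(diff(ages_mya) >= 0)) stop("ages must strictly decrease with group index")
  structure(list(clades = clades, ages_mya = ages_mya,
                 evalue_threshold = evalue_threshold),
            class = "temporal_group_scheme")
}

#' @export
print.temporal_group_scheme <- function(x, ...) {
  cat("Temporal group scheme:", length(x$clades) + 1L, "groups,",
      "e-value threshold", format(x$evalue_threshold), "\n")
  for (i in seq_along(x$clades))
    cat("  TG", i, " (", x$ages_mya[i], " Mya): ",
        paste(x$clades[[i]], collapse = ", "), "\n", sep = "")
  cat("  TG", length(x$clades) + 1L, " (", x$ages_mya[length(x$ages_mya)],
      " Mya): no qualifying homolog\n", sep = "")
  invisible(x)
}

#' Assign temporal groups from homology hits
#'
#' Each gene is assigned the oldest clade (smallest group index) in which
#' it has at least one hit with e-value at or below the scheme threshold.
#' Genes with no qualifying hit in any clade fall into the newest group
#' (lineage-specific). Hits in species unknown to the scheme are counted
#' and ignored.
#'
#' @param hits data frame from \code{\link{read_hit_table}}.
#' @param scheme a \code{\link{temporal_group_scheme}}.
#' @param genes optional gene universe; genes absent from \code{hits}
#'   receive the newest group.
#' @return named integer vector of group indices (1 = oldest); attribute
#'   \code{"log"} counts ignored unknown-species hits.
#' @export
assign_temporal_groups <- function(hits, scheme, genes = NULL) {
  if (!length(scheme$clades)) stop("empty temporal group scheme")
  n_groups <- length(scheme$clades) + 1L
  species2group <- unlist(lapply(seq_along(scheme$clades), function(i)
    setNames(rep(i, length(scheme$clades[[i]])), scheme$clades[[i]])))
  grp <- species2group[hits$species]
  unknown <- sum(is.na(grp) | !(hits$species %in% names(species2group)))
  qual <- !is.na(grp) & hits$evalue <= scheme$evalue_threshold
  best <- tapply(grp[qual], hits$query[qual], min)
  universe <- sort(unique(c(names(best), unique(hits$query), genes)))
  out <- setNames(rep(n_groups, length(universe)), universe)
  out[names(best)] <- as.integer(best)
  out <- setNames(as.integer(out), universe)
  attr(out, "log") <- list(unknown_species_hits = unknown)
  out
}

#' Single-linkage duplication clusters from self-similarity hits
#'
#' Clusters genes by transitive nucleotide similarity: genes joined by any
#' chain of hits at or below the e-value threshold share a cluster
#' (connected components of the symmetrized similarity graph). Clusters of
#' two or more genes carry evidence of historic duplication.
#'
#' @param self_hits data frame from \code{\link{read_hit_table}}; query and
#'   subject are drawn from the same gene universe. A-vs-A rows are
#'   ignored.
#' @param threshold e-value threshold (default 1e-25).
#' @param genes optional gene universe; genes without hits become
#'   singleton clusters.
#' @return an object of class \code{duplication_clusters}: list with
#'   \code{membership} (named integer vector), \code{clusters} (list of
#'   gene ID vectors) and \code{threshold}.
#' @export
build_duplication_clusters <- function(self_hits, threshold = 1e-25,
                                       genes = NULL) {
  use <- self_hits$evalue <= threshold & self_hits$query != self_hits$subject
  universe <- sort(unique(c(self_hits$query, self_hits$subject, genes)))
  g <- igraph::make_empty_graph(n = length(universe), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = universe)
  if (any(use))
    g <- igraph::add_edges(g, t(cbind(match(self_hits$query[use], universe),
                                      match(self_hits$subject[use], universe))))
  comp <- igraph::components(g)
  membership <- setNames(as.integer(comp$membership), universe)
  clusters <- split(universe, membership)
  stopifnot(sum(lengths(clusters)) == length(universe))
  structure(list(membership = membership, clusters = unname(clusters),
                 threshold = threshold),
            class = "duplication_clusters")
}

#' @export
print.duplication_clusters <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat("Duplication clusters at threshold", format(x$threshold), ":",
      length(sz), "clusters over", sum(sz), "genes;",
      sum(sz >= 2), "multi-gene clusters\n")
  invisible(x)
}

#' Genes in multi-gene duplication clusters
#' @param clusters a \code{duplication_clusters} object.
#' @return character vector of genes with duplication evidence.
#' @export
duplicated_genes <- function(clusters) {
  unlist(clusters$clusters[lengths(clusters$clusters) >= 2L],
         use.names = FALSE)
}

#' Per-group omega summary with a Kruskal-Wallis test
#'
#' Summarizes the strength of selective constraint (omega = Ka/Ks) per
#' temporal group and tests for a difference in location across groups.
#'
#' @param omega named numeric vector of omega values.
#' @param groups named integer vector of temporal groups.
#' @return list with \code{summary} (data frame: group, n, mean_omega,
#'   median_omega), \code{H}, \code{df} and \code{p}.
#' @export
omega_by_group <- function(omega, groups) {
  ids <- intersect(names(omega), names(groups))
  v <- omega[ids]; g <- groups[ids]
  keep <- is.finite(v)
  v <- v[keep]; g <- g[keep]
  if (!length(v)) stop("no finite omega values")
  if (length(unique(g)) < 2L) stop("need omega values in at least 2 groups")
  kw <- kruskal.test(v, factor(g))
  summ <- data.frame(
    group = sort(unique(g)),
    n = as.integer(table(factor(g))),
    mean_omega = as.numeric(tapply(v, factor(g), mean)),
    median_omega = as.numeric(tapply(v, factor(g), stats::median)))
  list(summary = summ, H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value)
}
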