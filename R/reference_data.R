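# Published human PPI study summary tables bundled as plain-text data.
# These are group-level summaries (the underlying gene-level data are not
# redistributable); they support reconstruction checks such as the
# pair-count-weighted per-group network distances and the functional
# distance vs age correlation.

#' Published human PPI study reference tables
#'
#' Loads the bundled group-level summary tables of the human PPI study:
#' per-group properties (age, gene counts, mean degree, mean clustering
#' coefficient, mean omega), the 6 x 6 average network distance matrix and
#' the 6 x 6 average functional distance matrix. The group matrices carry
#' population pair counts derived from the in-network gene counts
#' (N_m N_n off-diagonal, N_m (N_m - 1) / 2 within a group), which is what
#' per-group weighted reconstructions need.
#'
#' @return list with \code{tg_summary} (data frame),
#'   \code{network_distance} and \code{functional_distance} (both
#'   \code{\link{group_matrix}}), and \code{ages_mya}.
#' @export
reference_human_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "netphylo",
                                  mustWork = TRUE)
  summ <- read.delim(path("human_tg_summary.tsv"), comment.char = "#",
                     header = FALSE,
                     col.names = c("group", "age_mya", "n_genome",
                                   "n_network", "mean_degree",
                                   "mean_clustering", "mean_omega"))
  read_sym <- function(f, kind, N) {
    m <- as.matrix(read.delim(path(f), comment.char = "#", row.names = 1L,
                              check.names = FALSE))
    counts <- outer(N, N)
    diag(counts) <- N * (N - 1) / 2
    group_matrix(m, counts, kind = kind)
  }
  N <- summ$n_network
  list(tg_summary = summ,
       network_distance = read_sym("human_network_distance.tsv",
                                   "network_distance", N),
       functional_distance = read_sym("human_functional_distance.tsv",
                                      "functional_distance", N),
       ages_mya = summ$age_mya)
}

#' Per-group mean distance to all other proteins, reconstructed
#'
#' Reconstructs each group's average shortest-path distance to every other
#' protein in the network from the group-pair distance matrix and the
#' in-network group sizes: the row mean weighted by the number of partner
#' proteins each cell represents (N_n for other groups, N_m - 1 within the
#' group).
#'
#' @param gm a \code{\link{group_matrix}} of network distances.
#' @param n_network in-network gene counts per group.
#' @return named numeric vector of per-group means.
#' @export
per_group_distance_reconstruction <- function(gm, n_network) {
  k <- nrow(gm$values)
  stopifnot(length(n_network) == k)
  out <- vapply(seq_len(k), function(m) {
    w <- n_network
    w[m] <- n_network[m] - 1
    sum(gm$values[m, ] * w) / sum(w)
  }, 0)
  setNames(out, rownames(gm$values))
}
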