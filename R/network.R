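#' Construct a cleaned PPI network from an edge table
#'
#' Builds an undirected simple graph over gene identifiers. Self-loops and
#' duplicate edges (including reversed duplicates, since edges are
#' unordered) are removed and counted in the cleaning log.
#'
#' @param edges two-column character matrix or data frame of gene ID pairs.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node IDs to include.
#' @return An object of class \code{ppi_network}: a list with elements
#'   \code{graph} (an \pkg{igraph} graph), \code{n_nodes}, \code{n_edges}
#'   and \code{cleaning_log} (counts of removed \code{self_loops} and
#'   \code{duplicates}).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("edge table needs at least two columns")
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2L)
  self <- edges[, 1L] == edges[, 2L]
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  # canonical order so (A,B) and (B,A) collapse
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  a <- a[!dup]; b <- b[!dup]
  ids <- sort(unique(c(a, b, as.character(nodes))))
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  if (length(setdiff(ids, igraph::V(g)$name)))
    g <- igraph::add_vertices(g, length(setdiff(ids, igraph::V(g)$name)),
                              name = setdiff(ids, igraph::V(g)$name))
  structure(list(
    graph = g,
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    cleaning_log = list(self_loops = n_self, duplicates = n_dup)
  ), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  cl <- x$cleaning_log
  if (cl$self_loops + cl$duplicates > 0)
    cat("  cleaned at load:", cl$self_loops, "self-loops,",
        cl$duplicates, "duplicate edges\n")
  invisible(x)
}

#' Node identifiers of a network
#' @param net a \code{ppi_network}.
#' @return character vector of gene IDs.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' Edge list of a network
#' @param net a \code{ppi_network}.
#' @return two-column character matrix, one row per undirected edge.
#' @export
network_edges <- function(net) igraph::as_edgelist(net$graph)

#' Node degrees
#' @param net a \code{ppi_network}.
#' @return named integer vector of degrees.
#' @export
network_degree <- function(net) igraph::degree(net$graph)

#' Restrict a network to a subset of nodes
#' @param net a \code{ppi_network}.
#' @param keep character vector of node IDs to retain.
#' @return a \code{ppi_network} induced on \code{keep}.
#' @export
induced_network <- function(net, keep) {
  g <- igraph::induced_subgraph(net$graph, intersect(network_nodes(net), keep))
  out <- list(graph = g, n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
              cleaning_log = net$cleaning_log)
  class(out) <- "ppi_network"
  out
}

#' Largest connected component of a network
#' @param net a \code{ppi_network}.
#' @return a \code{ppi_network}; the number of dropped nodes is recorded in
#'   attribute \code{"n_dropped"}.
#' @export
largest_component <- function(net) {
  comp <- igraph::components(net$graph)
  keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  out <- induced_network(net, keep)
  attr(out, "n_dropped") <- net$n_nodes - out$n_nodes
  out
}

#' Symmetric group-by-group summary matrix
#'
#' Holds per-cell averages (functional distance, network distance or
#' interaction density) over pairs of temporal groups, together with the
#' number of pairs contributing to each cell. Cells with zero contributing
#' pairs are \code{NA} (missing), never zero.
#'
#' @param values symmetric numeric matrix (typically 6 x 6).
#' @param pair_counts symmetric matrix of contributing-pair counts.
#' @param kind one of \code{"functional_distance"},
#'   \code{"network_distance"}, \code{"interaction_density"}.
#' @return an object of class \code{group_matrix}.
#' @export
group_matrix <- function(values, pair_counts,
                         kind = c("functional_distance", "network_distance",
                                  "interaction_density")) {
  kind <- match.arg(kind)
  values <- as.matrix(values); pair_counts <- as.matrix(pair_counts)
  stopifnot(nrow(values) == ncol(values),
            all(dim(values) == dim(pair_counts)))
  if (!isTRUE(all.equal(values, t(values), check.attributes = FALSE)))
    stop("group matrix values must be symmetric")
  values[pair_counts == 0] <- NA_real_
  k <- nrow(values)
  labs <- paste0("TG", seq_len(k))
  dimnames(values) <- dimnames(pair_counts) <- list(labs, labs)
  structure(list(values = values, pair_counts = pair_counts, kind = kind),
            class = "group_matrix")
}

#' @export
print.group_matrix <- function(x, digits = 3, ...) {
  cat("Group matrix (", x$kind, "), ", nrow(x$values), " groups\n", sep = "")
  print(round(x$values, digits))
  invisible(x)
}

# mean of `mat` cell values over group pairs; within-group pairs counted
# once, self-pairs excluded; non-finite entries (unreachable, missing) are
# excluded from means but reflected in the coverage attribute. Aggregation
# runs through rowsum() so the dendrogram permutation loop stays cheap.
group_pair_means <- function(mat, groups, kind) {
  ids <- intersect(rownames(mat), names(groups))
  mat <- mat[ids, ids, drop = FALSE]
  grp <- groups[ids]
  lev <- sort(unique(grp))
  f <- factor(grp, levels = lev)
  k <- length(lev)
  nsz <- as.integer(table(f))
  ok <- is.finite(mat)
  diag(ok) <- FALSE
  m0 <- mat
  m0[!ok] <- 0
  sums <- t(rowsum(t(rowsum(m0, f)), f))           # ordered-pair sums
  cnts <- t(rowsum(t(rowsum(ok + 0, f)), f))       # ordered-pair counts
  # within-group cells: each unordered pair counted twice in ordered sums
  diag(sums) <- diag(sums) / 2
  diag(cnts) <- diag(cnts) / 2
  vals <- ifelse(cnts > 0, sums / cnts, NA_real_)
  tot <- outer(nsz, nsz)
  diag(tot) <- nsz * (nsz - 1) / 2
  gm <- group_matrix(vals, cnts, kind = kind)
  attr(gm, "coverage") <- ifelse(tot > 0, cnts / tot, NA_real_)
  attr(gm, "group_levels") <- lev
  gm
}
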