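# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, O(n^3) enumeration) so they cannot
# share a code path with the implementation they check.

# Erdos-Renyi style random edge list over n nodes
random_edge_table <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

# adjacency matrix from a ppi_network
adj_matrix <- function(net) {
  ids <- network_nodes(net)
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  el <- network_edges(net)
  A[el] <- 1L
  A[el[, c(2, 1), drop = FALSE]] <- 1L
  A
}

# O(n^3) clustering coefficient by triple enumeration
oracle_clustering <- function(net) {
  A <- adj_matrix(net)
  ids <- rownames(A)
  sapply(ids, function(v) {
    nb <- ids[A[v, ] == 1L]
    k <- length(nb)
    if (k < 2) return(NA_real_)
    tri <- 0L
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      tri <- tri + A[nb[i], nb[j]]
    2 * tri / (k * (k - 1))
  })
}

# Floyd-Warshall all-pairs shortest paths
oracle_distances <- function(net) {
  A <- adj_matrix(net)
  n <- nrow(A)
  D <- ifelse(A == 1L, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# naive per-cell double loop over group pairs of a value matrix
oracle_group_means <- function(mat, groups) {
  ids <- intersect(rownames(mat), names(groups))
  lev <- sort(unique(groups[ids]))
  k <- length(lev)
  vals <- cnts <- matrix(NA_real_, k, k)
  for (m in seq_len(k)) for (n in m:k) {
    gm <- ids[groups[ids] == lev[m]]
    gn <- ids[groups[ids] == lev[n]]
    v <- c()
    for (u in gm) for (w in gn) {
      if (u == w) next
      if (m == n && u > w) next
      val <- mat[u, w]
      if (is.finite(val)) v <- c(v, val)
    }
    vals[m, n] <- vals[n, m] <- if (length(v)) mean(v) else NA_real_
    cnts[m, n] <- cnts[n, m] <- length(v)
  }
  list(values = vals, counts = cnts)
}

# direct pair-enumeration interaction density
oracle_density <- function(net, groups) {
  ids <- network_nodes(net)
  A <- adj_matrix(net)
  lev <- sort(unique(groups[ids]))
  k <- length(lev)
  I <- E <- matrix(0, k, k)
  for (m in seq_len(k)) for (n in m:k) {
    gm <- ids[groups[ids] == lev[m]]
    gn <- ids[groups[ids] == lev[n]]
    icnt <- ecnt <- 0
    for (u in gm) for (w in gn) {
      if (u == w) next
      if (m == n && u > w) next
      ecnt <- ecnt + 1
      icnt <- icnt + A[u, w]
    }
    I[m, n] <- I[n, m] <- icnt
    E[m, n] <- E[n, m] <- ecnt
  }
  list(I = I, E = E, D = ifelse(E > 0, I / E, NA_real_))
}

# transitive-closure duplication clusters by repeated sweep (union-find
# by fixpoint iteration)
oracle_clusters <- function(pairs, universe) {
  lab <- setNames(seq_along(universe), universe)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) {
        old <- max(lab[a], lab[b])
        lab[lab == old] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(universe, lab)
}

# a tiny hand-built ontology:
#   root (BP)
#    +- sA   +- sB   +- sC          (sub-roots)
#    sA <- m1 ; sA,sB <- m2 ; sC <- m3 ; m3 <- leaf1
# plus one MF root with child f1, and one obsolete BP term
tiny_obo <- function() {
  structure(list(
    terms = data.frame(
      id = c("GO:ROOT", "GO:SA", "GO:SB", "GO:SC", "GO:M1", "GO:M2",
             "GO:M3", "GO:L1", "GO:OBS", "GO:FROOT", "GO:F1"),
      name = c("biological_process", "sub A", "sub B", "sub C", "mid 1",
               "mid 2", "mid 3", "leaf 1", "gone", "molecular_function",
               "func 1"),
      namespace = c(rep("biological_process", 9),
                    rep("molecular_function", 2)),
      obsolete = c(rep(FALSE, 8), TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE),
    parents = list(
      "GO:ROOT" = character(0),
      "GO:SA" = "GO:ROOT", "GO:SB" = "GO:ROOT", "GO:SC" = "GO:ROOT",
      "GO:M1" = "GO:SA", "GO:M2" = c("GO:SA", "GO:SB"), "GO:M3" = "GO:SC",
      "GO:L1" = "GO:M3", "GO:OBS" = "GO:ROOT",
      "GO:FROOT" = character(0), "GO:F1" = "GO:FROOT")),
    class = "obo_ontology")
}

# serialize any obo_ontology fixture to a temp file
obo_tempfile <- function(obo = tiny_obo()) {
  f <- tempfile(fileext = ".obo")
  write_toy_obo(obo, f)
  f
}

gaf_tempfile <- function(rows) {
  # rows: data.frame(gene, qualifier, term, aspect)
  f <- tempfile(fileext = ".gaf")
  con <- file(f, "w")
  writeLines("!gaf-version: 2.2", con)
  for (i in seq_len(nrow(rows)))
    writeLines(paste("DB", rows$gene[i], rows$gene[i], rows$qualifier[i],
                     rows$term[i], "REF:0", "IEA", "", rows$aspect[i], "",
                     "", "protein", "taxon:9606", "20120101", "DB",
                     sep = "\t"), con)
  close(con)
  f
}

# small grouped network: cycle + chords over 12 nodes, 3 groups
small_grouped_net <- function(seed = 42, n = 12, p = 0.3, k_groups = 3) {
  net <- ppi_network(random_edge_table(n, p, seed))
  ids <- network_nodes(net)
  groups <- setNames(rep(seq_len(k_groups), length.out = length(ids)), ids)
  list(net = net, groups = groups)
}
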