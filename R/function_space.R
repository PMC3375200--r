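# Functional distance machinery: sub-root annotation vectors, Mahalanobis
# distance with a regularized covariance, Resnik semantic distance,
# group-level functional distance matrices and the dendrogram permutation
# test.

#' Build the sub-root binary annotation matrix
#'
#' Projects each gene's annotations onto the sub-root level of the
#' ontology: X[g, t] = 1 iff sub-root term t (a direct child of the
#' namespace root) is an ancestor-or-self of any term annotated to g over
#' the is_a graph. Using only sub-root terms avoids redundancy from the
#' ontology hierarchy. The term covariance matrix is estimated over all
#' genes supplied (the annotation universe), capturing the dependence
#' between functional terms that the Mahalanobis distance accounts for;
#' when singular a small ridge is added to the diagonal before inversion,
#' with a Moore-Penrose pseudoinverse fallback.
#'
#' @param annotations named list gene ID -> term IDs (from
#'   \code{\link{read_annotations}}).
#' @param obo an \code{obo_ontology} (or path to an OBO file).
#' @param namespace \code{"biological_process"} or
#'   \code{"molecular_function"}.
#' @param ridge ridge epsilon added to the covariance diagonal when it is
#'   singular (default 1e-6).
#' @return object of class \code{annotation_matrix}: list with \code{X}
#'   (binary genes x terms matrix), \code{terms}, \code{genes},
#'   \code{cov}, \code{cov_inverse}, \code{regularization} (0 when no
#'   ridge was needed) and \code{zero_rows} (genes with no sub-root term).
#' @export
build_annotation_matrix <- function(annotations, obo,
                                    namespace = c("biological_process",
                                                  "molecular_function"),
                                    ridge = 1e-6) {
  namespace <- match.arg(namespace)
  if (!inherits(obo, "obo_ontology")) obo <- read_obo(obo)
  subroots <- sub_root_terms(obo, namespace)
  if (!length(subroots)) stop("namespace root has no children: ", namespace)
  all_terms <- unique(unlist(annotations, use.names = FALSE))
  anc <- term_ancestors(obo, intersect(all_terms, obo$terms$id))
  genes <- names(annotations)
  X <- matrix(0, length(genes), length(subroots),
              dimnames = list(genes, subroots))
  for (g in genes) {
    ts <- annotations[[g]]
    hit <- intersect(unique(unlist(anc[intersect(ts, names(anc))],
                                   use.names = FALSE)), subroots)
    if (length(hit)) X[g, hit] <- 1
  }
  zero_rows <- genes[rowSums(X) == 0]
  S <- cov(X)
  regularization <- 0
  Sinv <- NULL
  if (rcond_ok(S)) {
    Sinv <- try(solve(S), silent = TRUE)
    if (inherits(Sinv, "try-error")) Sinv <- NULL
  }
  if (is.null(Sinv)) {
    S_r <- S + diag(ridge, nrow(S))
    regularization <- ridge
    if (rcond_ok(S_r)) {
      Sinv <- try(solve(S_r), silent = TRUE)
      if (inherits(Sinv, "try-error")) Sinv <- NULL
    }
    if (is.null(Sinv)) Sinv <- MASS::ginv(S_r)
    S <- S_r
  }
  dimnames(Sinv) <- dimnames(S)
  structure(list(X = X, terms = subroots, genes = genes, cov = S,
                 cov_inverse = Sinv, regularization = regularization,
                 zero_rows = zero_rows),
            class = "annotation_matrix")
}

rcond_ok <- function(S, tol = 1e-10) {
  rc <- tryCatch(rcond(S), error = function(e) 0)
  is.finite(rc) && rc > tol
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat("Annotation matrix:", nrow(x$X), "genes x", ncol(x$X),
      "sub-root terms\n")
  if (length(x$zero_rows))
    cat("  ", length(x$zero_rows), "genes with no sub-root annotation\n")
  if (x$regularization > 0)
    cat("  covariance ridge-regularized (epsilon =",
        format(x$regularization), ")\n")
  invisible(x)
}

#' Mahalanobis distance between two annotation vectors
#'
#' sqrt((x - y)' S^{-1} (x - y)), where S^{-1} is the (possibly
#' regularized) inverse covariance of the annotation terms. Reduces to
#' Euclidean distance when the covariance is the identity.
#'
#' @param x,y numeric vectors of equal length.
#' @param cov_inverse inverse covariance matrix.
#' @return nonnegative scalar.
#' @export
mahalanobis_distance <- function(x, y, cov_inverse) {
  if (length(x) != length(y)) stop("dimension mismatch: ", length(x),
                                   " vs ", length(y))
  if (length(x) != nrow(cov_inverse)) stop("vector/covariance dimension mismatch")
  d <- x - y
  sqrt(max(0, drop(t(d) %*% cov_inverse %*% d)))
}

#' All pairwise Mahalanobis functional distances
#'
#' Computes the full genes x genes distance matrix via the quadratic-form
#' expansion d^2(x, y) = q(x) + q(y) - 2 x' S^{-1} y with
#' q(x) = x' S^{-1} x, evaluated blockwise as matrix products.
#'
#' @param am an \code{\link{annotation_matrix}}.
#' @param genes optional subset of genes.
#' @return symmetric numeric matrix of distances with gene dimnames.
#' @export
pairwise_functional_distances <- function(am, genes = NULL) {
  X <- am$X
  if (!is.null(genes)) X <- X[intersect(genes, rownames(X)), , drop = FALSE]
  M <- X %*% am$cov_inverse %*% t(X)
  q <- diag(M)
  d2 <- outer(q, q, "+") - 2 * M
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  d
}

#' Information content of ontology terms from an annotation corpus
#'
#' p(term) is the fraction of annotated genes whose is_a-propagated
#' annotation set contains the term (so every ancestor of an annotated
#' term counts as annotated); IC = -log2 p. The base-2 logarithm matches
#' the 1/2^x transform used to turn Resnik similarity into a distance, so
#' two identical single-term genes get distance 2^-IC. A natural-log
#' variant is available.
#'
#' @param annotations named list gene ID -> term IDs.
#' @param obo an \code{obo_ontology}.
#' @param log_base 2 (default) or \code{exp(1)}.
#' @return named numeric vector of IC values for every term observed in
#'   the propagated corpus.
#' @export
term_ic <- function(annotations, obo, log_base = 2) {
  anc <- term_ancestors(obo, intersect(unique(unlist(annotations)),
                                       obo$terms$id))
  prop <- lapply(annotations, function(ts)
    unique(unlist(anc[intersect(ts, names(anc))], use.names = FALSE)))
  n <- sum(lengths(prop) > 0)
  if (n == 0) stop("no annotated genes")
  counts <- table(unlist(prop, use.names = FALSE))
  p <- as.numeric(counts) / n
  setNames(-log(p, base = log_base), names(counts))
}

#' Resnik semantic distance between two genes
#'
#' The Resnik similarity of two terms is the information content of their
#' most informative common ancestor; gene similarity is the maximum over
#' all annotation term pairs, and the distance is (1/2)^similarity, which
#' lies in (0, 1]. Genes sharing only the root (IC 0) get distance 1.
#'
#' @param gene_a,gene_b gene IDs.
#' @param annotations named list gene ID -> term IDs.
#' @param obo an \code{obo_ontology}.
#' @param ic precomputed \code{\link{term_ic}} (recomputed if missing).
#' @return distance in (0, 1], or \code{NA} if either gene has no terms.
#' @export
resnik_gene_distance <- function(gene_a, gene_b, annotations, obo,
                                 ic = NULL) {
  if (is.null(ic)) ic <- term_ic(annotations, obo)
  ta <- annotations[[gene_a]]; tb <- annotations[[gene_b]]
  if (!length(ta) || !length(tb)) return(NA_real_)
  anc <- term_ancestors(obo, intersect(unique(c(ta, tb)), obo$terms$id))
  sim <- 0
  for (u in intersect(ta, names(anc))) for (v in intersect(tb, names(anc))) {
    common <- intersect(anc[[u]], anc[[v]])
    common <- intersect(common, names(ic))
    if (length(common)) sim <- max(sim, max(ic[common]))
  }
  0.5^sim
}

#' Pairwise Resnik distances for a gene set
#' @inheritParams resnik_gene_distance
#' @param genes gene IDs.
#' @return symmetric matrix of Resnik distances (NA where undefined).
#' @export
pairwise_resnik_distances <- function(genes, annotations, obo, ic = NULL) {
  if (is.null(ic)) ic <- term_ic(annotations, obo)
  anc <- term_ancestors(obo, intersect(unique(unlist(annotations[genes])),
                                       obo$terms$id))
  # per-gene best-IC ancestor profile: max IC among ancestors-or-self,
  # per ancestor term; gene-pair sim = max over shared ancestor terms
  prof <- lapply(genes, function(g) {
    ts <- intersect(annotations[[g]], names(anc))
    a <- unique(unlist(anc[ts], use.names = FALSE))
    a <- intersect(a, names(ic))
    setNames(ic[a], a)
  })
  n <- length(genes)
  d <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    if (!length(prof[[i]])) next
    for (j in i:n) {
      if (!length(prof[[j]])) next
      common <- intersect(names(prof[[i]]), names(prof[[j]]))
      sim <- if (length(common)) max(ic[common]) else 0
      d[i, j] <- d[j, i] <- 0.5^sim
    }
  }
  d
}

#' Group-by-group average functional distance matrix
#'
#' Cell (m, n) is the mean functional distance over gene pairs with one
#' gene in temporal group m and one in n; within-group pairs are counted
#' once and self-pairs excluded.
#'
#' @param distmat symmetric pairwise functional distance matrix (gene
#'   dimnames), e.g. from \code{\link{pairwise_functional_distances}}.
#' @param groups named integer vector of temporal groups.
#' @return a \code{\link{group_matrix}} of kind \code{functional_distance}.
#' @export
tg_functional_matrix <- function(distmat, groups) {
  group_pair_means(distmat, groups, kind = "functional_distance")
}

#' Agglomerative dendrogram of groups with a label-permutation test
#'
#' Clusters the group-level functional distance matrix and tests whether
#' the observed tree is tighter than expected if genes carried random
#' group labels. The statistic is the summed merge heights of the tree;
#' smaller means shorter functional distances along the tree, i.e. more
#' structure. The null permutes the gene-to-group labels (preserving group
#' sizes), rebuilds the group matrix from the same pairwise distances and
#' reclusters; p = (1 + #\{null <= observed\}) / (reps + 1), one-sided.
#'
#' @param distmat pairwise functional distance matrix.
#' @param groups named integer vector of temporal groups.
#' @param linkage \code{"average"} (default), \code{"single"} or
#'   \code{"complete"}.
#' @param reps permutations (default 1000).
#' @param seed optional RNG seed.
#' @return object of class \code{dendrogram_result}: list with
#'   \code{tree} (hclust), \code{statistic}, \code{null} (numeric
#'   vector), \code{p}, \code{reps}, and the observed
#'   \code{group_matrix}.
#' @export
dendrogram_with_permutation <- function(distmat, groups,
                                        linkage = c("average", "single",
                                                    "complete"),
                                        reps = 1000, seed = NULL) {
  linkage <- match.arg(linkage)
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- intersect(rownames(distmat), names(groups))
  groups <- groups[ids]
  gm <- tg_functional_matrix(distmat, groups)
  tree_stat <- function(g) {
    m <- group_pair_means(distmat, g, kind = "functional_distance")$values
    if (anyNA(m)) return(list(tree = NULL, stat = NA_real_))
    hc <- hclust(as.dist(m), method = linkage)
    list(tree = hc, stat = sum(hc$height))
  }
  obs <- tree_stat(groups)
  if (is.na(obs$stat)) stop("group matrix has empty cells; cannot cluster")
  if (max(obs$tree$height) - min(obs$tree$height) < .Machine$double.eps^0.5)
    warning("degenerate (all-equal) group matrix; ties broken deterministically")
  null <- vapply(seq_len(reps), function(i) {
    perm <- setNames(sample(groups), names(groups))
    tree_stat(perm)$stat
  }, 0)
  null <- null[!is.na(null)]
  p <- (1 + sum(null <= obs$stat)) / (length(null) + 1)
  structure(list(tree = obs$tree, statistic = obs$stat, null = null,
                 p = p, reps = reps, group_matrix = gm, linkage = linkage),
            class = "dendrogram_result")
}

#' @export
print.dendrogram_result <- function(x, ...) {
  cat("Group dendrogram (", x$linkage, " linkage): summed merge height = ",
      format(x$statistic, digits = 4), "\n", sep = "")
  cat("Permutation test:", x$reps, "reps, p =", format(x$p, digits = 3), "\n")
  invisible(x)
}

#' Are two leaves siblings in a dendrogram?
#' @param tree an \code{hclust} over group labels.
#' @param a,b leaf labels.
#' @return \code{TRUE} iff a and b are merged directly with each other.
#' @export
leaves_are_siblings <- function(tree, a, b) {
  ia <- -match(a, tree$labels); ib <- -match(b, tree$labels)
  any(apply(tree$merge, 1L, function(r) all(sort(r) == sort(c(ia, ib)))))
}

#' Correlation between group functional distance and group age difference
#'
#' Spearman correlation between the upper-triangle cells of the group
#' functional distance matrix (diagonal included by default, with age
#' difference 0) and the corresponding group age differences. By default
#' ages enter on the rank scale (group index), which is the natural scale
#' for a rank correlation with six tied age levels; absolute Mya
#' differences are available via \code{age_scale = "mya"} (note the two
#' scales rank pair differences differently because the Mya gaps between
#' groups are uneven).
#'
#' @param gm a \code{\link{group_matrix}} of functional distances.
#' @param ages_mya group ages (used when \code{age_scale = "mya"}).
#' @param age_scale \code{"rank"} (default) or \code{"mya"}.
#' @param include_diagonal include the 6 within-group cells (default
#'   \code{TRUE}; 21 pairs for 6 groups).
#' @return list with \code{rho}, \code{p}, \code{n_cells}.
#' @export
corr_funcdist_vs_agediff <- function(gm, ages_mya = NULL,
                                     age_scale = c("rank", "mya"),
                                     include_diagonal = TRUE) {
  age_scale <- match.arg(age_scale)
  k <- nrow(gm$values)
  age <- if (age_scale == "mya") {
    if (is.null(ages_mya)) stop("ages_mya required for age_scale = 'mya'")
    ages_mya[seq_len(k)]
  } else seq_len(k)
  diffm <- abs(outer(age, age, "-"))
  sel <- upper.tri(gm$values, diag = include_diagonal)
  x <- gm$values[sel]; y <- diffm[sel]
  if (anyNA(x)) stop("group matrix has missing cells")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_cells = sum(sel))
}

#' Mean functional distance profile over network distance
#'
#' Bins gene pairs by their network (shortest-path) distance and reports
#' the mean functional distance per bin; network distances at or above
#' \code{cap} are pooled into one bin. Also reports the global Spearman
#' correlation between the two distances over all (reachable) pairs. For
#' large networks pairs can be subsampled with a seeded sampler.
#'
#' @param funcdist pairwise functional distance matrix.
#' @param netdist pairwise network distance matrix (same gene universe).
#' @param cap pooling threshold (default 8: bins 1..7 and ">= 8").
#' @param sample_pairs optional number of pairs to subsample.
#' @param seed RNG seed for subsampling.
#' @return list with \code{profile} (data frame: network_distance,
#'   mean_funcdist, n_pairs), \code{rho}, \code{p}, \code{n_pairs_used}.
#' @export
funcdist_by_network_distance <- function(funcdist, netdist, cap = 8,
                                         sample_pairs = NULL, seed = NULL) {
  ids <- intersect(rownames(funcdist), rownames(netdist))
  fd <- funcdist[ids, ids]; nd <- netdist[ids, ids]
  sel <- upper.tri(fd)
  f <- fd[sel]; d <- nd[sel]
  keep <- is.finite(f) & is.finite(d) & d > 0
  f <- f[keep]; d <- d[keep]
  if (!is.null(sample_pairs) && sample_pairs < length(f)) {
    if (!is.null(seed)) set.seed(seed)
    take <- sample.int(length(f), sample_pairs)
    f <- f[take]; d <- d[take]
  }
  dbin <- pmin(d, cap)
  lev <- sort(unique(dbin))
  prof <- data.frame(
    network_distance = lev,
    mean_funcdist = as.numeric(tapply(f, factor(dbin, levels = lev), mean)),
    n_pairs = as.integer(table(factor(dbin, levels = lev))))
  ct <- suppressWarnings(cor.test(f, d, method = "spearman", exact = FALSE))
  list(profile = prof, rho = unname(ct$estimate), p = ct$p.value,
       n_pairs_used = length(f))
}
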