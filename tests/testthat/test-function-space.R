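# Annotation vectors, Mahalanobis/Resnik distances, group functional
# matrices, dendrogram permutation test, correlation operations.

test_that("sub-root projection propagates annotations up the is_a graph", {
  obo <- tiny_obo()
  ann <- list(gA = "GO:SA",            # direct sub-root annotation
              gB = "GO:M2",            # grandchild with two sub-root parents
              gC = "GO:L1",            # deep leaf under sC
              gD = character(0))       # unannotated
  am <- build_annotation_matrix(ann, obo, "biological_process")
  expect_equal(sort(colnames(am$X)), c("GO:SA", "GO:SB", "GO:SC"))
  expect_equal(unname(am$X["gA", c("GO:SA", "GO:SB", "GO:SC")]), c(1, 0, 0))
  expect_equal(unname(am$X["gB", c("GO:SA", "GO:SB", "GO:SC")]), c(1, 1, 0))
  expect_equal(unname(am$X["gC", c("GO:SA", "GO:SB", "GO:SC")]), c(0, 0, 1))
  expect_equal(am$zero_rows, "gD")
})

test_that("sub-root matrix equals an independent DAG-closure computation", {
  set.seed(14)
  obo <- tiny_obo()
  pool <- c("GO:SA", "GO:SB", "GO:SC", "GO:M1", "GO:M2", "GO:M3", "GO:L1")
  ann <- lapply(setNames(1:30, sprintf("g%02d", 1:30)), function(i)
    sample(pool, sample(0:3, 1)))
  am <- build_annotation_matrix(ann, obo, "biological_process")
  # independent oracle: explicit parent-following per annotated term
  up <- function(t) {
    out <- t
    frontier <- t
    while (length(frontier)) {
      frontier <- unlist(obo$parents[frontier], use.names = FALSE)
      out <- union(out, frontier)
    }
    out
  }
  for (g in names(ann)) {
    closure <- unique(unlist(lapply(ann[[g]], up)))
    for (t in c("GO:SA", "GO:SB", "GO:SC"))
      expect_equal(unname(am$X[g, t]), as.numeric(t %in% closure))
  }
})

test_that("covariance inverse satisfies the pseudoinverse identity", {
  set.seed(15)
  ann <- lapply(setNames(1:40, sprintf("g%02d", 1:40)), function(i)
    sample(c("GO:M1", "GO:M2", "GO:L1", "GO:SA"), sample(1:3, 1)))
  am <- build_annotation_matrix(ann, tiny_obo(), "biological_process")
  S <- am$cov; Si <- am$cov_inverse
  expect_equal(S %*% Si %*% S, S, tolerance = 1e-8)
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_true(all(eigen(S, only.values = TRUE)$values > -1e-10))
})

test_that("Mahalanobis distance matches the explicit linear-solve oracle", {
  expect_equal(mahalanobis_distance(c(1, 0), c(1, 0), diag(2)), 0)
  expect_equal(mahalanobis_distance(c(1, 0), c(0, 1), diag(2)), sqrt(2))
  S <- matrix(c(2, 0.5, 0.2, 0.5, 1, 0.3, 0.2, 0.3, 1.5), 3, 3)
  x <- c(1, 0, 1); y <- c(0, 1, 1)
  d_oracle <- sqrt(drop(t(x - y) %*% solve(S, x - y)))
  expect_equal(mahalanobis_distance(x, y, solve(S)), d_oracle,
               tolerance = 1e-12)
  expect_error(mahalanobis_distance(c(1, 0), c(1, 0, 0), diag(2)),
               "dimension mismatch")
})

test_that("identity covariance reduces Mahalanobis to Euclidean", {
  set.seed(16)
  p <- 12
  for (i in 1:1000) {
    x <- rbinom(p, 1, 0.4); y <- rbinom(p, 1, 0.4)
    expect_equal(mahalanobis_distance(x, y, diag(p)),
                 sqrt(sum((x - y)^2)), tolerance = 1e-10)
  }
})

test_that("pairwise distance matrix agrees with the per-pair computation", {
  set.seed(17)
  ann <- lapply(setNames(1:20, sprintf("g%02d", 1:20)), function(i)
    sample(c("GO:M1", "GO:M2", "GO:M3", "GO:L1", "GO:SB"), sample(1:3, 1)))
  am <- build_annotation_matrix(ann, tiny_obo(), "biological_process")
  fd <- pairwise_functional_distances(am)
  for (i in sample(20, 5)) for (j in sample(20, 5)) {
    expect_equal(fd[i, j],
                 mahalanobis_distance(am$X[i, ], am$X[j, ], am$cov_inverse),
                 tolerance = 1e-8)
    expect_equal(fd[i, j], fd[j, i])
    expect_gte(fd[i, j], 0)
  }
})

test_that("Resnik distances follow the IC definition on closed forms", {
  obo <- tiny_obo()
  # 4 genes; p(GO:M1-with-descendants) = 1/4 -> IC = 2 bits
  ann_ic <- list(g1 = "GO:M1", g3 = "GO:SB", g4 = "GO:SC", g5 = "GO:L1")
  ic <- term_ic(ann_ic, obo)
  expect_equal(unname(ic["GO:ROOT"]), 0)              # p = 1
  expect_equal(unname(ic["GO:M1"]), 2)                # p = 1/4
  # identical single-term genes with p(term) = 1/4 -> distance 0.25
  expect_equal(resnik_gene_distance("g1", "g1", ann_ic, obo, ic), 0.25)
  # genes sharing only the root -> sim 0, distance 1
  expect_equal(resnik_gene_distance("g3", "g4", ann_ic, obo, ic), 1)
})

test_that("pairwise Resnik equals the exhaustive ancestor-pair oracle", {
  set.seed(18)
  obo <- tiny_obo()
  pool <- c("GO:SA", "GO:SB", "GO:SC", "GO:M1", "GO:M2", "GO:M3", "GO:L1")
  ann <- lapply(setNames(1:12, sprintf("g%02d", 1:12)), function(i)
    sample(pool, sample(1:3, 1)))
  ic <- term_ic(ann, obo)
  anc <- term_ancestors(obo)
  oracle <- function(a, b) {
    sim <- 0
    for (u in ann[[a]]) for (v in ann[[b]]) {
      common <- intersect(anc[[u]], anc[[v]])
      common <- intersect(common, names(ic))
      if (length(common)) sim <- max(sim, max(ic[common]))
    }
    0.5^sim
  }
  d <- pairwise_resnik_distances(names(ann), ann, obo, ic)
  for (a in names(ann)) for (b in names(ann))
    expect_equal(d[a, b], oracle(a, b), tolerance = 1e-12)
  expect_true(all(d > 0 & d <= 1))
})

test_that("group functional matrix equals the double-loop oracle", {
  set.seed(19)
  ann <- lapply(setNames(1:50, sprintf("g%02d", 1:50)), function(i)
    sample(c("GO:M1", "GO:M2", "GO:M3", "GO:L1", "GO:SB"), sample(1:2, 1)))
  am <- build_annotation_matrix(ann, tiny_obo(), "biological_process")
  fd <- pairwise_functional_distances(am)
  groups <- setNames(rep(1:5, 10), names(ann))
  gm <- tg_functional_matrix(fd, groups)
  oracle <- oracle_group_means(fd, groups)
  expect_equal(unname(gm$values), oracle$values, tolerance = 1e-10)
  expect_equal(unname(gm$pair_counts), oracle$counts)

  # identical annotations -> all distances zero
  ann0 <- lapply(setNames(1:12, sprintf("h%02d", 1:12)), function(i) "GO:M1")
  am0 <- build_annotation_matrix(ann0, tiny_obo(), "biological_process")
  fd0 <- pairwise_functional_distances(am0)
  gm0 <- tg_functional_matrix(fd0, setNames(rep(1:3, 4), names(ann0)))
  expect_true(all(gm0$values == 0))
})

test_that("two groups with disjoint single terms sit sqrt(2) apart (identity cov)", {
  X <- rbind(diag(2)[rep(1, 4), ], diag(2)[rep(2, 4), ])
  rownames(X) <- sprintf("g%d", 1:8)
  am <- list(X = X, cov_inverse = diag(2))
  fd <- pairwise_functional_distances(am)
  gm <- tg_functional_matrix(fd, setNames(rep(1:2, each = 4), rownames(X)))
  expect_equal(gm$values["TG1", "TG2"], sqrt(2))
  expect_equal(gm$values["TG1", "TG1"], 0)
})

test_that("dendrogram permutation test finds planted structure, not noise", {
  set.seed(20)
  # planted age gradient: term carriage probability decays with the
  # distance between a gene's group and the term's home group, so nearby
  # groups are functionally closer (graded structure, not disjoint blocks)
  genes <- sprintf("g%03d", 1:120)
  groups <- setNames(rep(1:6, each = 20), genes)
  home <- rep(1:6, 2)
  X <- matrix(0, 120, 12, dimnames = list(genes, sprintf("t%02d", 1:12)))
  for (i in seq_along(genes))
    X[i, ] <- as.numeric(runif(12) < 0.7 * exp(-0.5 * abs(groups[i] - home)))
  fd <- pairwise_functional_distances(list(X = X, cov_inverse = diag(12)))
  res <- dendrogram_with_permutation(fd, groups, reps = 99, seed = 1)
  expect_lte(res$p, 0.05)
  expect_equal(length(res$tree$height), 5)               # 6 leaves, 5 merges
  expect_true(all(diff(res$tree$height) >= -1e-9))       # nondecreasing
  expect_gt(res$p, 0)

  # random labels: p should not be extreme (single-run sanity)
  perm <- setNames(sample(groups), genes)
  res0 <- dendrogram_with_permutation(fd, perm, reps = 99, seed = 2)
  expect_gt(res0$p, 0.01)
})

test_that("functional-distance/age correlation behaves on closed forms", {
  ages <- c(990, 450, 360, 310, 90, 50)
  # matrix equal to the group-index differences -> rho = 1
  m <- abs(outer(1:6, 1:6, "-")) + 0  # diagonal zero
  gm <- group_matrix(m, matrix(1, 6, 6), kind = "functional_distance")
  expect_equal(corr_funcdist_vs_agediff(gm)$rho, 1, tolerance = 1e-10)
  expect_equal(corr_funcdist_vs_agediff(gm, ages, age_scale = "mya",
                                        include_diagonal = FALSE)$n_cells, 15)
  # permuted cells: |rho| small on average over replicates
  set.seed(23)
  rhos <- replicate(40, {
    v <- matrix(0, 6, 6)
    v[upper.tri(v, diag = TRUE)] <- sample(m[upper.tri(m, diag = TRUE)])
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
    corr_funcdist_vs_agediff(
      group_matrix(v, matrix(1, 6, 6), "functional_distance"))$rho
  })
  expect_lt(abs(mean(rhos)), 0.25)
})

test_that("funcdist-by-network-distance profile pools and subsamples correctly", {
  sg <- small_grouped_net(seed = 55, n = 30, p = 0.12)
  nd <- all_pairs_distances(sg$net)
  ids <- network_nodes(sg$net)
  # constant functional distance -> flat profile
  fdc <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  diag(fdc) <- 0
  prof <- funcdist_by_network_distance(fdc, nd, cap = 4)
  expect_true(all(prof$profile$mean_funcdist == 1))
  expect_true(all(prof$profile$network_distance <= 4))
  # exhaustive vs subsampled agree within Monte-Carlo error
  set.seed(56)
  fdr <- matrix(runif(length(ids)^2), length(ids),
                dimnames = list(ids, ids))
  fdr <- (fdr + t(fdr)) / 2; diag(fdr) <- 0
  full <- funcdist_by_network_distance(fdr, nd)
  sub <- funcdist_by_network_distance(fdr, nd, sample_pairs = 200, seed = 3)
  expect_equal(sub$n_pairs_used, 200)
  expect_equal(mean(sub$profile$mean_funcdist),
               mean(full$profile$mean_funcdist), tolerance = 0.15)
})
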