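# Rewiring nulls, hub group distances, the distance-2 baseline,
# controlled correlations and enrichment statistics.

test_that("rewiring preserves the degree sequence exactly", {
  for (s in 1:3) {
    net <- ppi_network(random_edge_table(40, 0.1, seed = s))
    rw <- rewire_degree_preserving(net, n_swaps_per_edge = 10, seed = s)
    expect_equal(network_degree(rw)[network_nodes(net)],
                 network_degree(net))
    expect_equal(rw$n_edges, net$n_edges)
  }
  # 4-cycle: swaps keep 2-regularity
  cyc <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
  rw <- rewire_degree_preserving(cyc, seed = 1)
  expect_true(all(network_degree(rw) == 2))
})

test_that("rewiring scrambles most edges of a duplication-divergence network", {
  sim <- simulate_network(generator_config(n_final = 500, seed = 3))
  rw <- rewire_degree_preserving(sim$net, n_swaps_per_edge = 10, seed = 4)
  expect_lt(attr(rw, "edge_overlap"), 0.3)
})

test_that("hub group distance equals a naive per-hub double loop", {
  set.seed(30)
  sg <- small_grouped_net(seed = 61, n = 40, p = 0.2)
  ids <- network_nodes(sg$net)
  fd <- matrix(runif(length(ids)^2, 1, 3), length(ids),
               dimnames = list(ids, ids))
  fd <- (fd + t(fd)) / 2; diag(fd) <- 0
  for (excl in c(FALSE, TRUE)) {
    res <- suppressWarnings(
      hub_group_distance(sg$net, sg$groups, fd, hub_min_degree = 5,
                         exclude_interacting = excl))
    A <- adj_matrix(sg$net)
    deg <- rowSums(A)
    hubs <- names(deg)[deg >= 5]
    for (h in hubs) {
      partners <- ids[A[h, ] == 1]
      vals <- c()
      for (i in seq_along(partners)) for (j in seq_along(partners)) {
        if (i >= j) next
        u <- partners[i]; v <- partners[j]
        if (sg$groups[u] == sg$groups[v]) next
        if (excl && A[u, v] == 1) next
        vals <- c(vals, fd[u, v])
      }
      if (length(vals)) {
        expect_equal(unname(res$per_hub[h]), mean(vals), tolerance = 1e-12)
      } else {
        expect_false(h %in% names(res$per_hub))
      }
    }
  }
})

test_that("hubs with single-group or all-interacting partners are skipped", {
  # hub h: partners a (TG1), b (TG2), c (TG2); b-c also an edge
  net <- ppi_network(rbind(c("h", "a"), c("h", "b"), c("h", "c"),
                           c("b", "c")))
  groups <- setNames(c(1L, 1L, 2L, 2L), c("h", "a", "b", "c"))
  ids <- c("h", "a", "b", "c")
  fd <- matrix(2, 4, 4, dimnames = list(ids, ids)); diag(fd) <- 0
  res <- suppressWarnings(
    hub_group_distance(net, groups, fd, hub_min_degree = 3))
  # cross-group pairs only: (a,b), (a,c); (b,c) same group excluded
  expect_equal(unname(res$per_hub["h"]), 2)
  expect_equal(length(res$pair_values), 2)

  # partners all one group -> no qualifying pair -> hub skipped
  groups2 <- setNames(c(1L, 2L, 2L, 2L), ids)
  res2 <- suppressWarnings(
    hub_group_distance(net, groups2, fd, hub_min_degree = 3))
  expect_equal(res2$n_hubs, 0)
  expect_equal(res2$n_skipped_hubs, 1)
})

test_that("duplication-cluster exclusion removes genes before hub calling", {
  net <- ppi_network(rbind(c("h", "a"), c("h", "b"), c("h", "c")))
  groups <- setNames(c(1L, 1L, 2L, 3L), c("h", "a", "b", "c"))
  ids <- names(groups)
  fd <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(fd) <- 0
  dc <- build_duplication_clusters(
    data.frame(query = "a", subject = "b", species = "human",
               evalue = 1e-40, stringsAsFactors = FALSE),
    threshold = 1e-25, genes = ids)
  res <- suppressWarnings(
    hub_group_distance(net, groups, fd, hub_min_degree = 2,
                       exclude_dup_clusters = dc))
  # a and b removed; h keeps only partner c -> no pairs -> no hubs
  expect_equal(res$n_hubs, 0)
})

test_that("distance-2 baseline Z matches hand arithmetic and tracks shifts", {
  x <- c(1.0, 1.2, 0.8, 1.1, 0.9)           # hub pairs
  y <- c(1.5, 1.7, 1.6, 1.4, 1.8)           # distance-2 pool
  ids <- sprintf("n%d", 1:5)
  # synthetic matrices delivering exactly y as the d2 pool
  nd <- matrix(Inf, 5, 5, dimnames = list(ids, ids)); diag(nd) <- 0
  nd[1, 2] <- nd[2, 1] <- 2; nd[1, 3] <- nd[3, 1] <- 2
  nd[1, 4] <- nd[4, 1] <- 2; nd[2, 3] <- nd[3, 2] <- 2
  nd[2, 4] <- nd[4, 2] <- 2
  fd <- matrix(0, 5, 5, dimnames = list(ids, ids))
  fd[1, 2] <- fd[2, 1] <- y[1]; fd[1, 3] <- fd[3, 1] <- y[2]
  fd[1, 4] <- fd[4, 1] <- y[3]; fd[2, 3] <- fd[3, 2] <- y[4]
  fd[2, 4] <- fd[4, 2] <- y[5]
  res <- distance2_baseline(fd, nd, x)
  z_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 5 + var(y) / 5)
  expect_equal(res$z, z_hand, tolerance = 1e-12)
  expect_equal(res$n_d2_pairs, 5)
  expect_lt(res$z, 0)
  # same distribution both sides -> |Z| small on average
  set.seed(31)
  zs <- replicate(30, {
    xx <- rnorm(50); yy <- rnorm(50)
    (mean(xx) - mean(yy)) / sqrt(var(xx) / 50 + var(yy) / 50)
  })
  expect_lt(abs(mean(zs)), 0.5)
})

test_that("controlled correlation shrinks a confounded property and keeps df", {
  set.seed(32)
  n <- 600
  genes <- sprintf("g%03d", 1:n)
  groups <- setNames(sample(1:6, n, replace = TRUE), genes)
  # 7 overlapping categories tied to age (confounded): each category
  # spans two adjacent groups, property is a category-specific constant
  # plus noise, so the global correlation is negative while the
  # within-category correlation is ~ 0
  cat_of <- setNames(groups + sample(0:1, n, TRUE), genes)
  property <- setNames(1 - cat_of / 7 + rnorm(n, 0, 0.05), genes)
  categories <- split(genes, paste0("c", cat_of))
  res <- controlled_correlation(property, groups, categories)
  expect_lt(res$global_rho, -0.3)
  expect_lt(abs(res$controlled_rho), abs(res$global_rho) / 2)
  expect_equal(res$df, nrow(res$per_category) - 1)

  # property independent of categories: controlled ~ global, small t
  prop2 <- setNames(-0.1 * groups + rnorm(n, 0, 1), genes)
  cats2 <- split(genes, sample(paste0("r", 1:10), n, replace = TRUE))
  res2 <- controlled_correlation(prop2, groups, cats2)
  expect_equal(res2$controlled_rho, res2$global_rho, tolerance = 0.2)
})

test_that("hypergeometric enrichment matches the direct tail sum", {
  # background 20 genes, 5 carry the term; group of 5 genes, 4 carry it
  genes <- sprintf("g%02d", 1:20)
  X <- matrix(0, 20, 2, dimnames = list(genes, c("GO:T1", "GO:T2")))
  X[1:5, "GO:T1"] <- 1
  X[, "GO:T2"] <- 1                         # ubiquitous term
  am <- list(X = X)
  groups <- setNames(rep(2L, 20), genes)
  groups[c("g01", "g02", "g03", "g04", "g10")] <- 1L
  res <- group_term_enrichment(groups, am, background = genes)
  p_hand <- sum(dhyper(4:5, 5, 15, 5))
  row <- res$table[res$table$group == 1 & res$table$term == "GO:T1", ]
  expect_equal(row$p, p_hand, tolerance = 1e-12)
  # a term carried by everyone is never enriched
  ubi <- res$table[res$table$term == "GO:T2", ]
  expect_true(all(ubi$p == 1))
  expect_true(all(res$table$q >= res$table$p))
})

test_that("BH correction is monotone and calibrated on random groups", {
  set.seed(33)
  genes <- sprintf("g%03d", 1:200)
  X <- matrix(rbinom(200 * 10, 1, 0.3), 200, 10,
              dimnames = list(genes, sprintf("GO:%02d", 1:10)))
  groups <- setNames(sample(1:4, 200, replace = TRUE), genes)
  res <- group_term_enrichment(groups, list(X = X), background = genes)
  tab <- res$table
  for (g in unique(tab$group)) {
    fam <- tab[tab$group == g, ]
    fam <- fam[order(fam$p), ]
    # q nondecreasing in p within the family after step-up
    expect_true(all(diff(fam$q) >= -1e-12))
    expect_equal(fam$q, p.adjust(fam$p, "BH"), tolerance = 1e-12)
  }
  # random subsets: essentially nothing significant
  expect_lte(sum(tab$significant), 1)
})

test_that("property z-scores have correct sign, null center and errors", {
  set.seed(34)
  genes <- sprintf("g%03d", 1:300)
  property <- setNames(rnorm(300), genes)
  categories <- list(all = genes,
                     up = sample(genes, 40),
                     down = sample(genes, 40))
  property[categories$up] <- property[categories$up] + 1
  property[categories$down] <- property[categories$down] - 1
  res <- property_zscore_enrichment(property, categories)
  expect_gt(res$z[res$category == "up"], 0)
  expect_lt(res$z[res$category == "down"], 0)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  # the all-genes category has z exactly 0
  res_all <- property_zscore_enrichment(property, list(all = genes))
  expect_equal(res_all$z, 0)
  expect_error(property_zscore_enrichment(setNames(rep(1, 10),
                                                   sprintf("x%d", 1:10)),
                                          list(a = sprintf("x%d", 1:5))),
               "zero overall variance")
})
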