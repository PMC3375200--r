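# Generator properties: degree structure, group cuts, annotation
# structure, hit-table round trips, omega gradient, file emission.

test_that("pure duplication from a clique copies neighborhoods exactly", {
  cfg <- generator_config(n_final = 20, p_edge_retain = 1, p_new_edge = 0,
                          seed = 5)
  sim <- simulate_network(cfg)
  # with full retention and no extra edges, every child's neighborhood at
  # birth is its parent's; the graph stays connected and every new node's
  # degree is at least its parent's birth degree minus later additions --
  # the robust closed-form consequence is connectivity + no isolated nodes
  expect_equal(sim$net$n_nodes, 20)
  expect_true(all(network_degree(sim$net) >= 1))
  expect_equal(igraph::components(sim$net$graph)$no, 1)
  # child and parent are always adjacent-or-share-all-neighbors here:
  # with p_edge_retain = 1 the child copies the parent's full edge set
  for (child in names(sim$truth$parent)) {
    p <- sim$truth$parent[child]
    if (is.na(p)) next
    nb_c <- igraph::as_ids(igraph::neighbors(sim$net$graph, child))
    nb_p <- igraph::as_ids(igraph::neighbors(sim$net$graph, p))
    # parent's other neighbors are a subset of the child's neighbors
    expect_true(all(setdiff(nb_p, child) %in% union(nb_c, child)))
  }
})

test_that("default network is heavy-tailed with an age-degree gradient", {
  ratios <- rhos <- numeric(0)
  for (s in 1:5) {
    sim <- simulate_network(generator_config(n_final = 1000, seed = s))
    deg <- network_degree(sim$net)
    ratios <- c(ratios, mean(sort(deg, decreasing = TRUE)[1:100]) / median(deg))
    rhos <- c(rhos, cor(sim$truth$birth_time[names(deg)], deg,
                        method = "spearman"))
  }
  expect_gt(mean(ratios), 3)       # top decile much denser than the median
  expect_true(all(rhos < 0))       # earlier-born genes have higher degree
})

test_that("birth-time quantile cut yields balanced, ordered groups", {
  sim <- simulate_network(generator_config(n_final = 600, seed = 9))
  ga <- assign_groups_and_ages(sim$truth, generator_config(n_final = 600))
  sizes <- table(ga$groups)
  expect_equal(length(sizes), 6L)
  expect_true(max(sizes) - min(sizes) <= 6)  # near n/6 each (ties at cuts)
  # group index nondecreasing in birth time
  ord <- order(sim$truth$birth_time)
  expect_true(!is.unsorted(ga$groups[names(sim$truth$birth_time)[ord]]))
  # degenerate truth: too few distinct birth times
  expect_error(assign_groups_and_ages(
    list(birth_time = setNames(rep(1, 30), sprintf("g%d", 1:30))),
    generator_config()), "fewer distinct birth times")
})

test_that("emitted hit tables round-trip through the assignment machinery", {
  study <- simulate_ppi_study(generator_config(n_final = 400, seed = 11))
  g2 <- assign_temporal_groups(study$species_hits, study$scheme,
                               genes = names(study$groups))
  expect_equal(unname(g2[names(study$groups)]), unname(study$groups))
  dc <- build_duplication_clusters(study$self_hits,
                                   threshold = study$config$dup_threshold,
                                   genes = names(study$groups))
  oracle <- oracle_clusters(cbind(study$self_hits$query,
                                  study$self_hits$subject),
                            names(study$groups))
  key <- function(cl) sort(unname(sapply(cl, function(x)
    paste(sort(x), collapse = ","))))
  expect_equal(key(dc$clusters), key(oracle))
})

test_that("corrupting e-values causes at most a matching misassignment rate", {
  study <- simulate_ppi_study(generator_config(n_final = 400, seed = 12))
  hits <- study$species_hits
  set.seed(13)
  qualifying <- which(hits$evalue <= study$scheme$evalue_threshold)
  corrupt <- sample(qualifying, round(0.05 * length(qualifying)))
  hits$evalue[corrupt] <- 1e-5
  g2 <- assign_temporal_groups(hits, study$scheme, genes = names(study$groups))
  err <- mean(g2[names(study$groups)] != study$groups)
  expect_lte(err, 0.05 + 1e-9)
})

test_that("omega draws are nonnegative with a recoverable group gradient", {
  study <- simulate_ppi_study(generator_config(n_final = 800, seed = 14))
  expect_true(all(study$omega >= 0))
  res <- omega_by_group(study$omega, study$groups)
  expect_true(!is.unsorted(res$summary$mean_omega))
  expect_lt(res$p, 0.01)
  # slope zero: no gradient, Kruskal-Wallis well calibrated (spot check)
  study0 <- simulate_ppi_study(generator_config(n_final = 800, seed = 15,
                                                omega_slope = 0))
  res0 <- omega_by_group(study0$omega, study0$groups)
  expect_gt(res0$p, 0.001)
})

test_that("every emitted file parses back through the package readers", {
  study <- simulate_ppi_study(generator_config(n_final = 200, seed = 16))
  dir <- tempfile()
  expect_no_warning(write_study(study, dir))
  expect_no_warning({
    net <- read_edge_list(file.path(dir, "net.tsv"))
    hits <- read_hit_table(file.path(dir, "hits_species.tsv"))
    selfh <- read_hit_table(file.path(dir, "hits_self.tsv"))
    obo <- read_obo(file.path(dir, "toy.obo"))
    ann <- read_annotations(file.path(dir, "ann.gaf"), obo,
                            "biological_process")
    omega <- read_omega_table(file.path(dir, "omega.tsv"))
    groups <- read_groups(file.path(dir, "groups.tsv"))
  })
  expect_equal(net$n_edges, study$net$n_edges)
  expect_equal(sort(network_nodes(net)), sort(network_nodes(study$net)))
  expect_equal(groups, study$groups)
  expect_equal(unname(omega[names(study$omega)]), unname(study$omega),
               tolerance = 1e-6)
  for (g in sample(names(ann), 20))
    expect_setequal(ann[[g]], study$annotations[[g]])
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 16)
})

test_that("ablated generator plants no functional structure", {
  study <- simulate_ppi_study(generator_config(n_final = 400, seed = 17,
                                               age_gradient = 0,
                                               hub_coherence = 0))
  am <- build_annotation_matrix(study$annotations, study$obo)
  fd <- pairwise_functional_distances(am, genes = names(study$groups))
  gm <- tg_functional_matrix(fd, study$groups)
  res <- corr_funcdist_vs_agediff(gm)
  expect_gt(res$p, 0.001)   # no age signal to detect
})
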