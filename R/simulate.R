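# Duplication-divergence synthetic study generator. Every analysis stage
# gets inputs with planted, tunable structure: heavy-tailed degree
# distribution with an age-degree gradient, six birth-time groups,
# age-graded annotation vectors, functionally coherent hub neighborhoods,
# recorded duplication parentage and an omega gradient. Setting
# age_gradient = 0 and hub_coherence = 0 ablates all functional structure
# (pure null).

#' Configuration for the synthetic study generator
#'
#' Defaults produce a network of 1000 genes whose statistical features
#' mirror the human PPI study design: six temporal groups with the ages
#' used there, a duplication-divergence degree distribution, a clear
#' age gradient in the annotation space, coherent hub neighborhoods and an
#' omega (Ka/Ks) gradient across groups.
#'
#' @param n_final number of genes (>= 20).
#' @param p_edge_retain probability a duplicate keeps each parent edge.
#' @param p_new_edge scale of random new edges per duplicate (Poisson mean
#'   = p_new_edge x current mean degree).
#' @param group_boundaries five birth-time quantiles cutting genes into
#'   six temporal groups.
#' @param ages_mya six group ages, strictly decreasing.
#' @param n_terms number of sub-root functional terms in the toy ontology.
#' @param n_shared_terms core terms carried by every gene.
#' @param age_gradient decay rate of term-carriage probability per group
#'   step away from a term's home group; 0 ablates the age structure.
#' @param hub_coherence probability a planted hub's partner carries the
#'   hub's signature term set; 0 ablates hub coherence.
#' @param hub_term_count number of signature terms per planted hub (a
#'   hub's neighborhood emulates a functional module, e.g. a complex, so
#'   its members share several functions, not one).
#' @param hub_fraction fraction of top-degree nodes planted as hubs.
#' @param p_term_base baseline carriage probability of a non-core term at
#'   its home group.
#' @param omega_slope increase in mean omega per group index step.
#' @param p_dup_detect probability a recorded parent-child duplication
#'   leaves a detectable sequence-similarity trace in the self-hit table
#'   (genome-wide single-linkage clustering at stringent thresholds only
#'   captures a minority of historic duplications).
#' @param evalue_threshold,dup_threshold thresholds written into the
#'   emitted hit tables.
#' @param seed RNG seed governing the whole emission.
#' @return a list of class \code{generator_config}.
#' @export
generator_config <- function(n_final = 1000,
                             p_edge_retain = 0.4,
                             p_new_edge = 0.1,
                             group_boundaries = seq(1, 5) / 6,
                             ages_mya = c(990, 450, 360, 310, 90, 50),
                             n_terms = 30,
                             n_shared_terms = 2,
                             age_gradient = 0.3,
                             hub_coherence = 0.8,
                             hub_term_count = 3,
                             hub_fraction = 0.02,
                             p_term_base = 0.7,
                             omega_slope = 0.03,
                             p_dup_detect = 0.15,
                             evalue_threshold = 1e-20,
                             dup_threshold = 1e-25,
                             seed = 1) {
  stopifnot(n_final >= 20,
            p_edge_retain >= 0, p_edge_retain <= 1,
            p_new_edge >= 0,
            length(group_boundaries) == 5,
            all(group_boundaries > 0), all(group_boundaries < 1),
            !is.unsorted(group_boundaries),
            length(ages_mya) == 6, all(diff(ages_mya) < 0),
            n_terms >= 1, n_shared_terms >= 0, n_shared_terms < n_terms,
            age_gradient >= 0, hub_coherence >= 0, hub_coherence <= 1,
            omega_slope >= 0)
  if (age_gradient > 0 && n_terms < 6)
    stop("need n_terms >= 6 when age_gradient > 0")
  structure(as.list(environment()), class = "generator_config")
}

#' Grow a duplication-divergence network
#'
#' Starts from a 5-clique and repeatedly duplicates a uniformly chosen
#' node: the duplicate keeps each parent edge with probability
#' \code{p_edge_retain} and gains Poisson(\code{p_new_edge} x mean degree)
#' random extra edges. Birth times and parentage are recorded. The largest
#' connected component is kept (drop count logged in the truth record).
#'
#' @param config a \code{\link{generator_config}}.
#' @param seed optional override of \code{config$seed}.
#' @return list with \code{net} (a \code{\link{ppi_network}}) and
#'   \code{truth} (list: \code{birth_time}, \code{parent} named vectors,
#'   \code{n_dropped}).
#' @export
simulate_network <- function(config, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed else seed)
  n <- config$n_final
  gene_id <- function(i) sprintf("G%04d", i)
  nbr <- vector("list", n)       # adjacency as integer index lists
  seed_n <- 5L
  for (i in seq_len(seed_n)) nbr[[i]] <- setdiff(seq_len(seed_n), i)
  birth <- c(rep(0L, seed_n), seq_len(n - seed_n))
  parent <- rep(NA_integer_, n)
  for (child in (seed_n + 1L):n) {
    existing <- child - 1L
    par <- sample.int(existing, 1L)
    parent[child] <- par
    keep <- nbr[[par]][runif(length(nbr[[par]])) < config$p_edge_retain]
    mean_deg <- sum(lengths(nbr[1:existing])) / existing
    extra <- rpois(1L, config$p_new_edge * mean_deg)
    if (extra > 0)
      keep <- unique(c(keep, sample.int(existing, min(extra, existing))))
    keep <- setdiff(keep, child)
    # a disconnected duplicate gains one fallback edge to its parent
    if (!length(keep)) keep <- par
    nbr[[child]] <- keep
    for (k in keep) nbr[[k]] <- c(nbr[[k]], child)
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    js <- nbr[[i]][nbr[[i]] > i]
    if (length(js)) cbind(gene_id(i), gene_id(js)) else NULL
  }))
  net <- ppi_network(edges)
  net <- largest_component(net)
  keep_ids <- network_nodes(net)
  names(birth) <- names(parent) <- gene_id(seq_len(n))
  parent_id <- setNames(ifelse(is.na(parent), NA_character_,
                               gene_id(ifelse(is.na(parent), 1L, parent))),
                        names(parent))
  truth <- list(birth_time = birth[keep_ids],
                parent = parent_id[keep_ids],
                n_dropped = attr(net, "n_dropped"))
  if (net$n_nodes == 0) stop("parameters yielded an empty graph")
  list(net = net, truth = truth)
}

#' Cut birth times into temporal groups and attach ages
#'
#' Genes are split at the configured birth-time quantiles into six groups;
#' the earliest-born genes form group 1 (oldest). Group index is
#' nondecreasing in birth time by construction.
#'
#' @param truth truth record from \code{\link{simulate_network}}.
#' @param config a \code{\link{generator_config}}.
#' @return list with \code{groups} (named integer vector) and
#'   \code{ages_mya}.
#' @export
assign_groups_and_ages <- function(truth, config) {
  bt <- truth$birth_time
  if (length(unique(bt)) < 6L)
    stop("fewer distinct birth times than groups")
  cuts <- quantile(bt, probs = config$group_boundaries, type = 1)
  grp <- findInterval(bt, unique(c(cuts)), left.open = TRUE) + 1L
  # guard: quantile ties can merge boundaries; renumber to 1..k observed
  grp <- as.integer(factor(grp))
  list(groups = setNames(grp, names(bt)), ages_mya = config$ages_mya)
}

#' Simulate age-graded, hub-coherent functional annotations
#'
#' Emits a two-level toy ontology (one biological_process root with
#' \code{n_terms} sub-root children) and per-gene term assignments. Every
#' gene carries the \code{n_shared_terms} core terms. Each remaining term
#' has a home group (cycling over 1..6) and a gene carries it with
#' probability \code{p_term_base} x exp(-age_gradient x |group(gene) -
#' home(term)|), so between-group annotation distance grows with age
#' difference. Each planted hub (top \code{hub_fraction} of nodes by
#' degree) is assigned a signature set of \code{hub_term_count} non-core
#' terms (its neighborhood emulates a functional module); each partner
#' adopts the full signature with probability \code{hub_coherence}.
#'
#' @param net a \code{\link{ppi_network}}.
#' @param groups named integer group vector.
#' @param truth truth record (hub assignments are added to it in the
#'   returned value).
#' @param config a \code{\link{generator_config}}.
#' @return list with \code{annotations} (named list gene -> term IDs),
#'   \code{obo} (an \code{obo_ontology}), \code{truth} (with
#'   \code{planted_hubs} and \code{hub_terms} added).
#' @export
simulate_annotations <- function(net, groups, truth, config) {
  if (config$age_gradient > 0 && config$n_terms < 6)
    stop("need n_terms >= 6 when age_gradient > 0")
  nt <- config$n_terms
  root <- "GO:0000000"
  terms <- sprintf("GO:%07d", seq_len(nt))
  obo <- structure(list(
    terms = data.frame(
      id = c(root, terms),
      name = c("biological_process", sprintf("toy process %d", seq_len(nt))),
      namespace = "biological_process",
      obsolete = FALSE, stringsAsFactors = FALSE),
    parents = c(setNames(list(character(0)), root),
                setNames(rep(list(root), nt), terms))),
    class = "obo_ontology")
  genes <- network_nodes(net)
  core <- terms[seq_len(config$n_shared_terms)]
  free <- setdiff(terms, core)
  home <- setNames(((seq_along(free) - 1L) %% 6L) + 1L, free)
  ann <- lapply(genes, function(g) {
    p <- config$p_term_base *
      exp(-config$age_gradient * abs(groups[[g]] - home))
    c(core, free[runif(length(free)) < p])
  })
  names(ann) <- genes
  deg <- network_degree(net)
  n_hubs <- max(1L, round(config$hub_fraction * length(genes)))
  hubs <- names(sort(deg, decreasing = TRUE))[seq_len(n_hubs)]
  sig_size <- min(config$hub_term_count, length(free))
  hub_terms <- setNames(lapply(seq_len(n_hubs), function(i)
    sample(free, sig_size)), hubs)
  if (config$hub_coherence > 0) {
    for (h in hubs) {
      partners <- igraph::as_ids(igraph::neighbors(net$graph, h))
      share <- partners[runif(length(partners)) < config$hub_coherence]
      for (s in c(h, share)) ann[[s]] <- unique(c(ann[[s]], hub_terms[[h]]))
    }
  }
  truth$planted_hubs <- hubs
  truth$hub_terms <- hub_terms
  list(annotations = ann, obo = obo, truth = truth)
}

#' Write a two-level toy ontology as OBO
#' @param obo an \code{obo_ontology} (two-level, as emitted by
#'   \code{\link{simulate_annotations}}).
#' @param path output path.
#' @export
write_toy_obo <- function(obo, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(obo$terms))) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", obo$terms$id[i]), con)
    writeLines(paste0("name: ", obo$terms$name[i]), con)
    writeLines(paste0("namespace: ", obo$terms$namespace[i]), con)
    for (p in obo$parents[[obo$terms$id[i]]])
      writeLines(paste0("is_a: ", p), con)
    if (obo$terms$obsolete[i]) writeLines("is_obsolete: true", con)
    writeLines("", con)
  }
  invisible(path)
}

#' Simulate homology hit tables consistent with the planted groups
#'
#' The species hit table gives every gene of group g (g <= 5) one
#' qualifying hit (e-value well below threshold) in a species of clade g
#' and no qualifying hits in older clades; decoy hits with e-values above
#' the threshold are sprinkled into older clades. Group-6 genes get no
#' qualifying hit. The self-hit table contains one row per recorded
#' parent-child duplication with an e-value below the duplication
#' threshold for the detectable fraction (\code{p_dup_detect}) of
#' recorded duplications, so clusters recovered at that threshold equal
#' the connected components of the detectable parentage edges.
#'
#' @param groups named integer group vector.
#' @param truth truth record with \code{parent}.
#' @param config a \code{\link{generator_config}}.
#' @param scheme a \code{\link{temporal_group_scheme}} naming the clade
#'   species.
#' @param p_decoy probability of adding one above-threshold decoy hit in
#'   an older clade per gene.
#' @return list with \code{species_hits} and \code{self_hits} data frames
#'   (columns query, subject, species, evalue).
#' @export
simulate_hit_tables <- function(groups, truth, config,
                                scheme = temporal_group_scheme(
                                  evalue_threshold = config$evalue_threshold),
                                p_decoy = 0.3) {
  rows <- list()
  for (g in names(groups)) {
    tg <- groups[[g]]
    if (tg <= length(scheme$clades)) {
      sp <- sample(scheme$clades[[tg]], 1L)
      ev <- 10^-runif(1L, 25, 60)
      rows[[length(rows) + 1L]] <- data.frame(
        query = g, subject = paste0(sp, "|", g, "h"), species = sp,
        evalue = ev, stringsAsFactors = FALSE)
    }
    older <- seq_len(tg - 1L)
    if (length(older) && runif(1L) < p_decoy) {
      oc <- sample(older, 1L)
      sp <- sample(scheme$clades[[oc]], 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        query = g, subject = paste0(sp, "|", g, "d"), species = sp,
        evalue = 10^-runif(1L, 0, 15), stringsAsFactors = FALSE)
    }
  }
  species_hits <- do.call(rbind, rows)
  has_par <- !is.na(truth$parent) & truth$parent %in% names(groups) &
    runif(length(truth$parent)) < config$p_dup_detect
  self_hits <- data.frame(
    query = names(truth$parent)[has_par],
    subject = unname(truth$parent[has_par]),
    species = "human",
    evalue = 10^-runif(sum(has_par), 30, 60),
    stringsAsFactors = FALSE)
  list(species_hits = species_hits, self_hits = self_hits)
}

#' Simulate a per-gene omega table with a group gradient
#'
#' Omega is drawn from a Gamma distribution (shape 2) whose mean rises
#' linearly with group index: mean = 0.03 + omega_slope x (group - 1).
#' Older genes thus show stronger purifying selection.
#'
#' @param groups named integer group vector.
#' @param config a \code{\link{generator_config}}.
#' @return named numeric vector of omega values (all >= 0).
#' @export
simulate_omega <- function(groups, config) {
  mu <- 0.03 + config$omega_slope * (groups - 1)
  shape <- 2
  setNames(rgamma(length(groups), shape = shape, rate = shape / mu),
           names(groups))
}

#' Generate a complete synthetic study
#'
#' Runs the full generator: network, temporal groups, annotations and toy
#' ontology, hit tables, omega table. One seed governs the whole
#' emission.
#'
#' @param config a \code{\link{generator_config}}.
#' @return object of class \code{ppi_study}: list with \code{net},
#'   \code{groups}, \code{ages_mya}, \code{annotations}, \code{obo},
#'   \code{species_hits}, \code{self_hits}, \code{omega}, \code{scheme},
#'   \code{truth}, \code{config}.
#' @export
simulate_ppi_study <- function(config = generator_config()) {
  sim <- simulate_network(config)
  set.seed(config$seed + 1L)
  ga <- assign_groups_and_ages(sim$truth, config)
  set.seed(config$seed + 2L)
  annres <- simulate_annotations(sim$net, ga$groups, sim$truth, config)
  scheme <- temporal_group_scheme(evalue_threshold = config$evalue_threshold,
                                  ages_mya = config$ages_mya)
  set.seed(config$seed + 3L)
  hits <- simulate_hit_tables(ga$groups, annres$truth, config, scheme)
  set.seed(config$seed + 4L)
  omega <- simulate_omega(ga$groups, config)
  structure(list(net = sim$net, groups = ga$groups, ages_mya = ga$ages_mya,
                 annotations = annres$annotations, obo = annres$obo,
                 species_hits = hits$species_hits, self_hits = hits$self_hits,
                 omega = omega, scheme = scheme, truth = annres$truth,
                 config = config),
            class = "ppi_study")
}

#' @export
print.ppi_study <- function(x, ...) {
  cat("Synthetic PPI study:", x$net$n_nodes, "genes,", x$net$n_edges,
      "edges,", length(unique(x$groups)), "temporal groups\n")
  cat("  age gradient:", x$config$age_gradient,
      "| hub coherence:", x$config$hub_coherence,
      "| omega slope:", x$config$omega_slope, "\n")
  invisible(x)
}

#' Write a synthetic study to a directory of standard-format files
#'
#' Emits net.tsv (edge list), hits_species.tsv and hits_self.tsv
#' (4-column hit tables), ann.gaf, toy.obo, omega.tsv, groups.tsv and
#' truth.json. Every file parses back through the package readers.
#'
#' @param study a \code{ppi_study}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_edge_list(study$net, p("net.tsv"))
  write.table(study$species_hits, p("hits_species.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(study$self_hits, p("hits_self.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_gaf(study$annotations, p("ann.gaf"))
  write_toy_obo(study$obo, p("toy.obo"))
  write_omega_table(study$omega, p("omega.tsv"))
  write.table(data.frame(names(study$groups), study$groups),
              p("groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(birth_time = as.list(study$truth$birth_time),
         parent = as.list(study$truth$parent),
         planted_hubs = study$truth$planted_hubs,
         hub_terms = as.list(study$truth$hub_terms),
         seed = study$config$seed),
    p("truth.json"), auto_unbox = TRUE, null = "null", na = "null")
  invisible(dir)
}

#' Read a gene-to-group TSV written by \code{\link{write_study}}
#' @param path two-column TSV: gene ID, group index.
#' @return named integer vector.
#' @export
read_groups <- function(path) {
  lines <- read_lines_checked(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  fields <- split_fields(lines[keep])
  g <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  if (anyNA(g))
    stop("non-integer group at line ", which(keep)[which(is.na(g))[1L]],
         " of ", path)
  setNames(g, vapply(fields, `[`, "", 1L))
}
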