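# Minimal OBO 1.2/1.4 and GAF 2.x readers. Only the fields the analysis
# needs are parsed: term id, name, namespace, is_a parents, obsolescence.

#' Read an OBO ontology file
#'
#' Parses \code{[Term]} stanzas of an OBO 1.2/1.4 file, keeping the term
#' ID, name, namespace, \code{is_a} parents and obsolete flag. Other
#' relationship types (part_of etc.) are ignored: ancestor propagation in
#' this package runs over the \code{is_a} graph only.
#'
#' @param path path to the OBO file.
#' @return an object of class \code{obo_ontology}: list with
#'   \code{terms} (data frame: id, name, namespace, obsolete) and
#'   \code{parents} (named list: term ID to character vector of is_a
#'   parent IDs).
#' @export
read_obo <- function(path) {
  lines <- read_lines_checked(path)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas in ", path)
  stanza_ends <- c(term_starts[-1L] - 1L, length(lines))
  # non-Term stanzas ([Typedef]...) after a term truncate that term's block
  other <- which(startsWith(lines, "[") & lines != "[Term]")
  ids <- names <- namespaces <- character(length(term_starts))
  obsolete <- logical(length(term_starts))
  parents <- vector("list", length(term_starts))
  for (i in seq_along(term_starts)) {
    from <- term_starts[i] + 1L
    to <- stanza_ends[i]
    cut <- other[other >= from & other <= to]
    if (length(cut)) to <- min(cut) - 1L
    block <- lines[from:to]
    getval <- function(tag) {
      hit <- block[startsWith(block, paste0(tag, ":"))]
      sub("^[^:]+:\\s*", "", hit)
    }
    id <- getval("id")[1L]
    if (is.na(id)) next
    ids[i] <- id
    nm <- getval("name"); names[i] <- if (length(nm)) nm[1L] else ""
    ns <- getval("namespace"); namespaces[i] <- if (length(ns)) ns[1L] else ""
    obsolete[i] <- any(grepl("^true", getval("is_obsolete")))
    isa <- getval("is_a")
    parents[[i]] <- sub("\\s*!.*$", "", isa)
  }
  keep <- nzchar(ids)
  terms <- data.frame(id = ids[keep], name = names[keep],
                      namespace = namespaces[keep], obsolete = obsolete[keep],
                      stringsAsFactors = FALSE)
  structure(list(terms = terms,
                 parents = setNames(parents[keep], ids[keep])),
            class = "obo_ontology")
}

#' @export
print.obo_ontology <- function(x, ...) {
  cat("OBO ontology:", nrow(x$terms), "terms;",
      sum(x$terms$obsolete), "obsolete\n")
  for (ns in unique(x$terms$namespace))
    cat("  ", ns, ": ", sum(x$terms$namespace == ns & !x$terms$obsolete),
        " terms\n", sep = "")
  invisible(x)
}

#' Root term of a namespace
#' @param obo an \code{obo_ontology}.
#' @param namespace namespace string, e.g. \code{"biological_process"}.
#' @return the term ID of the (unique) non-obsolete term in the namespace
#'   with no is_a parent.
#' @export
namespace_root <- function(obo, namespace) {
  cand <- obo$terms$id[obo$terms$namespace == namespace & !obo$terms$obsolete]
  if (!length(cand)) stop("namespace has zero terms: ", namespace)
  roots <- cand[vapply(obo$parents[cand], length, 1L) == 0L]
  if (length(roots) != 1L)
    stop("namespace ", namespace, " has ", length(roots),
         " roots; expected exactly one")
  roots
}

#' Sub-root terms: the direct children of a namespace root
#' @inheritParams namespace_root
#' @return character vector of term IDs whose is_a parents include the
#'   namespace root.
#' @export
sub_root_terms <- function(obo, namespace) {
  root <- namespace_root(obo, namespace)
  ids <- obo$terms$id[obo$terms$namespace == namespace & !obo$terms$obsolete]
  sort(ids[vapply(obo$parents[ids], function(p) root %in% p, TRUE)])
}

#' Ancestor closure over the is_a graph
#'
#' @param obo an \code{obo_ontology}.
#' @param terms term IDs to close over (default: all non-obsolete).
#' @param include_self include each term in its own ancestor set.
#' @return named list: term ID to character vector of ancestor IDs.
#' @export
term_ancestors <- function(obo, terms = NULL, include_self = TRUE) {
  if (is.null(terms)) terms <- obo$terms$id[!obo$terms$obsolete]
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    memo[[id]] <- character(0)  # guard against is_a cycles
    ps <- obo$parents[[id]]
    ps <- ps[ps %in% names(obo$parents)]
    res <- unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    memo[[id]] <- res
    res
  }
  out <- lapply(terms, function(t) {
    a <- anc(t)
    if (include_self) unique(c(t, a)) else a
  })
  setNames(out, terms)
}

#' Read gene annotations from a GAF file
#'
#' Parses GAF 2.x rows, keeping the DB object ID (column 2), qualifier
#' (column 4), term ID (column 5) and aspect (column 9), and restricts to
#' one namespace. Rows with a \code{NOT} qualifier are excluded (standard
#' GAF semantics); all evidence codes are retained. Terms missing from the
#' ontology and obsolete terms are dropped with logged counts.
#'
#' @param gaf_path path to the GAF file.
#' @param obo_path path to the OBO file, or an already-parsed
#'   \code{obo_ontology}.
#' @param namespace \code{"biological_process"} or
#'   \code{"molecular_function"}.
#' @return named list mapping gene ID to a character vector of term IDs
#'   (possibly empty). Attribute \code{"log"} carries counts of rows
#'   excluded as NOT-qualified, unknown-term, obsolete-term or
#'   other-namespace.
#' @export
read_annotations <- function(gaf_path, obo_path,
                             namespace = c("biological_process",
                                           "molecular_function")) {
  namespace <- match.arg(namespace)
  obo <- if (inherits(obo_path, "obo_ontology")) obo_path else read_obo(obo_path)
  ns_terms <- obo$terms$id[obo$terms$namespace == namespace & !obo$terms$obsolete]
  if (!length(ns_terms)) stop("namespace has zero terms: ", namespace)
  lines <- read_lines_checked(gaf_path)
  keep <- nzchar(lines) & !startsWith(lines, "!")
  fields <- split_fields(lines[keep])
  bad <- which(vapply(fields, length, 1L) < 9L)
  if (length(bad))
    stop("GAF row with fewer than 9 columns at line ",
         which(keep)[bad[1L]], " of ", gaf_path)
  gene <- vapply(fields, `[`, "", 2L)
  qualifier <- vapply(fields, `[`, "", 4L)
  term <- vapply(fields, `[`, "", 5L)
  is_not <- grepl("(^|\\|)NOT($|\\|)", qualifier)
  known <- term %in% obo$terms$id
  obs <- known & term %in% obo$terms$id[obo$terms$obsolete]
  in_ns <- term %in% ns_terms
  use <- !is_not & in_ns
  log <- list(not_qualified = sum(is_not),
              unknown_term = sum(!known & !is_not),
              obsolete_term = sum(obs & !is_not),
              other_namespace = sum(known & !obs & !in_ns & !is_not))
  ann <- lapply(split(term[use], gene[use]), unique)
  # genes seen only in excluded rows still get an (empty) entry
  missing_genes <- setdiff(unique(gene), names(ann))
  ann[missing_genes] <- list(character(0))
  attr(ann, "log") <- log
  ann
}

#' Write annotations as a minimal GAF 2.2 file
#' @param annotations named list gene ID -> term IDs.
#' @param path output path.
#' @param aspect single-letter GO aspect code written in column 9
#'   (\code{"P"} or \code{"F"}).
#' @export
write_gaf <- function(annotations, path, aspect = "P") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  for (g in names(annotations)) {
    for (t in annotations[[g]]) {
      writeLines(paste("DB", g, g, "involved_in", t, "REF:0", "IEA", "",
                       aspect, "", "", "protein", "taxon:9606",
                       "20120101", "DB", "", "", sep = "\t"), con)
    }
  }
  invisible(path)
}
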