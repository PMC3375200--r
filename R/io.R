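# File readers and writers. All readers reject malformed input with an
# error naming the offending line; all cleaning is counted, never silent.

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(lines)))
    stop("empty file: ", path)
  lines
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a PPI edge list
#'
#' Reads either a plain two-column tab-separated edge list or a PSI-MI TAB
#' 2.5 file (interactor columns 1-2 are used; all other columns ignored).
#' Lines starting with \code{#} and, for PSI-MI TAB, a header line whose
#' first field starts with \code{"ID("} are skipped. The returned graph is
#' cleaned (no self-loops, no duplicate or reversed-duplicate edges) and
#' re-reading a written edge list is a fixed point.
#'
#' @param path path to the file.
#' @param format \code{"tsv"} or \code{"psimitab"}.
#' @return a \code{\link{ppi_network}}.
#' @export
read_edge_list <- function(path, format = c("tsv", "psimitab")) {
  format <- match.arg(format)
  lines <- read_lines_checked(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  if (format == "psimitab" && any(keep)) {
    first <- lines[which(keep)[1L]]
    if (startsWith(first, "ID(") || startsWith(first, "id("))
      keep[which(keep)[1L]] <- FALSE
  }
  fields <- split_fields(lines)
  bad <- which(keep & vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop("malformed edge row (fewer than 2 columns) at line ", bad[1L],
         " of ", path)
  rows <- fields[keep]
  if (length(rows) == 0L) stop("no edge rows in ", path)
  edges <- t(vapply(rows, function(f) f[1:2], character(2L)))
  ppi_network(edges)
}

#' Write a PPI edge list
#' @param net a \code{\link{ppi_network}}.
#' @param path output path (two-column TSV).
#' @export
write_edge_list <- function(net, path) {
  write.table(network_edges(net), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a homology hit table
#'
#' Accepts BLAST tabular output (outfmt 6: qseqid, sseqid, ..., evalue in
#' column 11) or a minimal four-column TSV (query, subject, species,
#' evalue). For BLAST-style input the subject species is taken from the
#' subject ID prefix before the first \code{"|"} unless \code{species_col}
#' is given. Column indices are configurable for non-standard layouts.
#'
#' @param path path to the hit table.
#' @param query_col,subject_col,evalue_col,species_col 1-based column
#'   indices; \code{species_col = NULL} derives species from the subject ID
#'   prefix. Defaults auto-detect 4-column (query, subject, species,
#'   evalue) versus 12-column BLAST layouts.
#' @return data frame with columns \code{query}, \code{subject},
#'   \code{species}, \code{evalue}.
#' @export
read_hit_table <- function(path, query_col = NULL, subject_col = NULL,
                           evalue_col = NULL, species_col = NULL) {
  lines <- read_lines_checked(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  fields <- split_fields(lines[keep])
  nf <- vapply(fields, length, 1L)
  if (is.null(query_col)) {
    if (all(nf == 4L)) {
      query_col <- 1L; subject_col <- 2L; species_col <- 3L; evalue_col <- 4L
    } else {
      query_col <- 1L; subject_col <- 2L; evalue_col <- 11L
    }
  }
  need <- max(query_col, subject_col, evalue_col,
              if (is.null(species_col)) 0L else species_col)
  bad <- which(nf < need)
  if (length(bad))
    stop("hit table row with fewer than ", need, " columns at line ",
         which(keep)[bad[1L]], " of ", path)
  query <- vapply(fields, `[`, "", query_col)
  subject <- vapply(fields, `[`, "", subject_col)
  ev_chr <- vapply(fields, `[`, "", evalue_col)
  evalue <- suppressWarnings(as.numeric(ev_chr))
  if (anyNA(evalue))
    stop("non-numeric e-value at line ",
         which(keep)[which(is.na(evalue))[1L]], " of ", path)
  if (any(evalue < 0))
    stop("negative e-value at line ",
         which(keep)[which(evalue < 0)[1L]], " of ", path)
  species <- if (is.null(species_col)) {
    sub("\\|.*$", "", subject)
  } else vapply(fields, `[`, "", species_col)
  data.frame(query = query, subject = subject, species = species,
             evalue = evalue, stringsAsFactors = FALSE)
}

#' Read a per-gene omega (Ka/Ks) table
#'
#' Two-column TSV: gene ID, omega. Omega is the ratio of nonsynonymous to
#' synonymous substitution rates and must be nonnegative.
#'
#' @param path path to the TSV (no header, or a header line starting with
#'   \code{#}).
#' @return named numeric vector of omega values.
#' @export
read_omega_table <- function(path) {
  lines <- read_lines_checked(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  fields <- split_fields(lines[keep])
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop("omega table row with fewer than 2 columns at line ",
         which(keep)[bad[1L]], " of ", path)
  vals <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(vals))
    stop("non-numeric omega at line ",
         which(keep)[which(is.na(vals))[1L]], " of ", path)
  if (any(vals < 0))
    stop("negative omega at line ",
         which(keep)[which(vals < 0)[1L]], " of ", path)
  setNames(vals, vapply(fields, `[`, "", 1L))
}

#' Write a per-gene omega table
#' @param omega named numeric vector.
#' @param path output path.
#' @export
write_omega_table <- function(omega, path) {
  write.table(data.frame(names(omega), unname(omega)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a group matrix as labelled TSV
#'
#' Values and pair counts are written as two blocks with TG row/column
#' labels; missing cells are written as \code{NA}.
#'
#' @param gm a \code{\link{group_matrix}}.
#' @param path output path.
#' @export
write_group_matrix <- function(gm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#kind\t", gm$kind), con)
  hdr <- paste(c("", colnames(gm$values)), collapse = "\t")
  writeLines("#values", con); writeLines(hdr, con)
  for (i in seq_len(nrow(gm$values)))
    writeLines(paste(c(rownames(gm$values)[i],
                       format(gm$values[i, ], digits = 17)), collapse = "\t"), con)
  writeLines("#pair_counts", con); writeLines(hdr, con)
  for (i in seq_len(nrow(gm$pair_counts)))
    writeLines(paste(c(rownames(gm$pair_counts)[i], gm$pair_counts[i, ]),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a group matrix written by \code{\link{write_group_matrix}}
#' @param path path to the TSV.
#' @return a \code{\link{group_matrix}}.
#' @export
read_group_matrix <- function(path) {
  lines <- read_lines_checked(path)
  kind <- sub("^#kind\t", "", lines[startsWith(lines, "#kind")][1L])
  parse_block <- function(tag) {
    at <- which(lines == tag)
    if (!length(at)) stop("missing block ", tag, " in ", path)
    hdr <- strsplit(lines[at + 1L], "\t")[[1L]][-1L]
    k <- length(hdr)
    rows <- lines[(at + 2L):(at + 1L + k)]
    m <- t(vapply(strsplit(rows, "\t"), function(f) {
      v <- suppressWarnings(as.numeric(f[-1L]))
      v
    }, numeric(k)))
    dimnames(m) <- list(vapply(strsplit(rows, "\t"), `[`, "", 1L), hdr)
    m
  }
  group_matrix(parse_block("#values"), parse_block("#pair_counts"), kind = kind)
}

#' Write a dendrogram (or any tree) to Newick
#'
#' @param tree an \code{hclust}, \code{dendrogram} or \pkg{ape}
#'   \code{phylo} object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "dendrogram")) tree <- as.hclust(tree)
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  if (!inherits(tree, "phylo")) stop("cannot convert tree to phylo")
  ape::write.tree(tree, file = path)
  invisible(path)
}
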