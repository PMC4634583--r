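#' Gene-to-GO-term annotation map for one aspect
#'
#' @param gene2terms named list: gene id -> character vector of term ids.
#' @param graph the [ontology_graph] of the matching aspect; every
#'   annotated term must exist in it (annotations to unknown terms are
#'   dropped with a message).
#' @param evidence_excluded character vector of evidence codes that were
#'   filtered out when reading (recorded for provenance, not enforced
#'   here).
#' @return object of class `annotation_map` with elements `gene2terms`,
#'   `aspect`, `evidence_excluded`, `unannotated` (genes passed in with
#'   zero surviving terms).
#' @export
annotation_map <- function(gene2terms, graph,
                           evidence_excluded = character(0)) {
  stopifnot(inherits(graph, "ontology_graph"))
  gene2terms <- lapply(gene2terms, function(tt) unique(as.character(tt)))
  dropped <- 0L
  gene2terms <- lapply(gene2terms, function(tt) {
    keep <- tt %in% graph$terms
    dropped <<- dropped + sum(!keep)
    tt[keep]
  })
  if (dropped > 0L) {
    message("annotation_map: dropped ", dropped,
            " annotation(s) to terms absent from the ", graph$aspect,
            " ontology")
  }
  structure(
    list(gene2terms = gene2terms,
         aspect = graph$aspect,
         evidence_excluded = as.character(evidence_excluded),
         unannotated = names(gene2terms)[lengths(gene2terms) == 0L]),
    class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map (%s): %d genes (%d unannotated)\n",
              x$aspect, length(x$gene2terms), length(x$unannotated)))
  invisible(x)
}

#' Read a GAF 2.x annotation file
#'
#' Uses GAF columns 2 (gene id), 5 (GO id), 7 (evidence code) and
#' 9 (aspect: P/C/F).  Lines starting with `!` are comments.
#'
#' @param path path to a GAF file.
#' @param graph [ontology_graph] selecting the aspect to keep.
#' @param exclude_evidence evidence codes (e.g. `"IEA"`) to drop; none
#'   are dropped by default.
#' @param normalize_ids uppercase gene ids and strip isoform suffixes
#'   (".1"); default TRUE so annotations match normalised network ids.
#' @return an [annotation_map].
#' @export
read_gaf <- function(path, graph, exclude_evidence = character(0),
                     normalize_ids = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) stop("no annotation rows in GAF file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9L)) stop("GAF rows must have >= 9 columns")
  gene <- vapply(fields, `[[`, character(1), 2L)
  go <- vapply(fields, `[[`, character(1), 5L)
  ev <- vapply(fields, `[[`, character(1), 7L)
  asp <- vapply(fields, `[[`, character(1), 9L)
  aspect_code <- c(BP = "P", CC = "C", MF = "F")[[graph$aspect]]
  keep <- asp == aspect_code & !(ev %in% exclude_evidence)
  if (normalize_ids) gene <- normalize_gene_ids(gene)
  g2t <- split(go[keep], gene[keep])
  annotation_map(g2t, graph, evidence_excluded = exclude_evidence)
}

#' Read a plain 2-column gene/term annotation table
#'
#' Alternative dialect to GAF: a headerless (or headered) tab-separated
#' table whose first column is the gene id and second the GO term id.
#' All rows are assumed to belong to the aspect of `graph`; rows whose
#' term is not in `graph` are dropped with a message.
#'
#' @inheritParams read_gaf
#' @param header whether the first row is a header (default FALSE).
#' @return an [annotation_map].
#' @export
read_gene_term_table <- function(path, graph, header = FALSE,
                                 normalize_ids = TRUE) {
  tab <- utils::read.delim(path, header = header,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("annotation table needs >= 2 columns")
  gene <- tab[[1]]
  if (normalize_ids) gene <- normalize_gene_ids(gene)
  annotation_map(split(tab[[2]], gene), graph)
}

#' Normalise gene/protein identifiers
#'
#' Uppercases locus identifiers and strips trailing isoform suffixes
#' such as `".1"`, so that transcript-level ids from different source
#' databases collapse onto one locus id.
#'
#' @param ids character vector of identifiers.
#' @return normalised character vector.
#' @export
normalize_gene_ids <- function(ids) {
  sub("\\.[0-9]+$", "", toupper(as.character(ids)))
}
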