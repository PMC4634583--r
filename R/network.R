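#' Integrate protein-protein interaction edge lists
#'
#' Builds one non-redundant undirected network from any number of edge
#' tables: `(a, b)` and `(b, a)` collapse onto the same unordered edge,
#' self-loops are dropped, and per-source membership is retained so a
#' source-by-source topology report can be produced.
#'
#' @param sources a named (or unnamed) list of data frames / matrices
#'   whose first two columns are interacting gene ids, or a single such
#'   table.
#' @param normalize_ids uppercase ids and strip isoform suffixes
#'   (default TRUE).
#' @return object of class `ppi_network`: elements `nodes`, `edges`
#'   (data frame `a`, `b` with `a < b` lexicographically), `sources`
#'   (logical membership matrix, one column per input), and `graph`
#'   (the [igraph::graph] representation).
#' @export
integrate_edge_lists <- function(sources, normalize_ids = TRUE) {
  if (is.data.frame(sources) || is.matrix(sources)) sources <- list(sources)
  if (!length(sources)) stop("no edge-list sources supplied")
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    names(sources) <- paste0("source", seq_along(sources))
  }
  canon <- lapply(sources, function(tab) {
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("edge table needs >= 2 columns of gene ids")
    a <- as.character(tab[[1]]); b <- as.character(tab[[2]])
    if (normalize_ids) { a <- normalize_gene_ids(a); b <- normalize_gene_ids(b) }
    keep <- a != b                              # drop self-loops
    a <- a[keep]; b <- b[keep]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    unique(paste(a, b, sep = "\r"))
  })
  all_keys <- sort(unique(unlist(canon)))
  if (!length(all_keys)) stop("integrated network is empty")
  membership <- vapply(canon, function(k) all_keys %in% k,
                       logical(length(all_keys)))
  membership <- matrix(membership, nrow = length(all_keys),
                       dimnames = list(NULL, names(sources)))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  edges <- data.frame(a = vapply(parts, `[[`, character(1), 1L),
                      b = vapply(parts, `[[`, character(1), 2L),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$a, edges$b)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, sources = membership,
                 graph = g),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins, %d interactions, %d source(s)\n",
              length(x$nodes), nrow(x$edges), ncol(x$sources)))
  invisible(x)
}

#' Read a 2-column tab-separated edge list
#'
#' @param path file path; headerless TSV whose first two columns are
#'   gene ids.  Extra columns are ignored.
#' @param header whether the first line is a header.
#' @return data frame with two character columns.
#' @export
read_edge_list <- function(path, header = FALSE) {
  tab <- utils::read.delim(path, header = header, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 2L) stop("edge list needs >= 2 columns: ", path)
  tab[, 1:2]
}

#' Read interactor pairs from a PSI-MITAB 2.5 file
#'
#' Extracts the primary identifiers from columns 1 and 2
#' (`db:accession` syntax; the accession part is returned).
#'
#' @param path path to a MITAB file.
#' @return 2-column data frame of interactor ids.
#' @export
read_mitab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) stop("MITAB rows must have >= 2 columns")
  acc <- function(x) sub("^[^:]*:", "", sub("\\|.*$", "", x))
  data.frame(a = acc(vapply(fields, `[[`, character(1), 1L)),
             b = acc(vapply(fields, `[[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

#' Weight a PPI network with gene semantic similarity
#'
#' Every edge receives the GO semantic similarity of its endpoint genes
#' for one aspect, producing a WPPIN.  Edges whose weight is missing
#' (an unannotated endpoint) or exactly zero are retained in the edge
#' table but marked non-traversable: path search never crosses them.
#'
#' @param net a [ppi_network][integrate_edge_lists].
#' @param annotations an [annotation_map] of the chosen aspect.
#' @param graph the [ontology_graph] of the same aspect.
#' @inheritParams gene_similarity
#' @return object of class `wppin`: the network plus `weights`
#'   (numeric, `NA` = missing), `traversable` (logical), `aspect`, the
#'   retained/dropped edge counts, and a prebuilt adjacency index used
#'   by the path search.
#' @export
weight_network <- function(net, annotations, graph,
                           combine = c("BMA", "max"),
                           factors = default_relation_factors()) {
  stopifnot(inherits(net, "ppi_network"))
  combine <- match.arg(combine)
  w <- mapply(function(a, b) {
    gene_similarity(a, b, annotations, graph, combine = combine,
                    factors = factors)
  }, net$edges$a, net$edges$b, USE.NAMES = FALSE)
  traversable <- !is.na(w) & w > 0
  if (!any(traversable)) {
    warning("no traversable edges: every edge weight is missing or zero")
  }
  out <- structure(
    c(unclass(net),
      list(weights = w, traversable = traversable, aspect = graph$aspect,
           n_retained = sum(traversable),
           n_dropped = sum(!traversable))),
    class = c("wppin", "ppi_network"))
  out$adjacency <- build_adjacency(out)
  out$path_cache <- new.env(parent = emptyenv())
  out
}

#' @export
print.wppin <- function(x, ...) {
  cat(sprintf(
    "wppin (%s): %d proteins, %d interactions (%d weighted, %d non-traversable)\n",
    x$aspect, length(x$nodes), nrow(x$edges), x$n_retained, x$n_dropped))
  invisible(x)
}

# integer adjacency over traversable edges, for the weighted BFS
build_adjacency <- function(net) {
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  nb <- vector("list", length(net$nodes))
  wt <- vector("list", length(net$nodes))
  for (i in seq_along(nb)) { nb[[i]] <- integer(0); wt[[i]] <- numeric(0) }
  keep <- which(net$traversable)
  ai <- idx[net$edges$a[keep]]; bi <- idx[net$edges$b[keep]]
  ww <- net$weights[keep]
  for (k in seq_along(keep)) {
    nb[[ai[k]]] <- c(nb[[ai[k]]], bi[k]); wt[[ai[k]]] <- c(wt[[ai[k]]], ww[k])
    nb[[bi[k]]] <- c(nb[[bi[k]]], ai[k]); wt[[bi[k]]] <- c(wt[[bi[k]]], ww[k])
  }
  list(index = idx, neighbors = nb, weights = wt)
}

#' Construct a WPPIN directly from explicit edge weights
#'
#' Convenience constructor used when weights come from a serialized
#' 3-column table rather than a fresh semantic-similarity computation.
#'
#' @param edges data frame with columns `a`, `b`, `weight` (`NA` for
#'   missing).
#' @param aspect aspect label to attach.
#' @return a `wppin` object.
#' @export
wppin_from_weights <- function(edges, aspect = "BP") {
  stopifnot(all(c("a", "b", "weight") %in% names(edges)))
  net <- integrate_edge_lists(list(weighted = edges[, c("a", "b")]))
  ea <- normalize_gene_ids(edges$a); eb <- normalize_gene_ids(edges$b)
  key_in <- paste(pmin(ea, eb), pmax(ea, eb), sep = "\r")
  key_net <- paste(net$edges$a, net$edges$b, sep = "\r")
  w <- as.numeric(edges$weight)[match(key_net, key_in)]
  traversable <- !is.na(w) & w > 0
  out <- structure(
    c(unclass(net),
      list(weights = w, traversable = traversable, aspect = aspect,
           n_retained = sum(traversable), n_dropped = sum(!traversable))),
    class = c("wppin", "ppi_network"))
  out$adjacency <- build_adjacency(out)
  out$path_cache <- new.env(parent = emptyenv())
  out
}

#' Serialize a weighted network to 3-column TSV
#'
#' @param net a `wppin`.
#' @param path output file; columns gene, gene, weight (`NA` for
#'   missing weights).
#' @export
write_wppin <- function(net, path) {
  stopifnot(inherits(net, "wppin"))
  utils::write.table(
    data.frame(a = net$edges$a, b = net$edges$b, weight = net$weights),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a weighted network from 3-column TSV
#'
#' @param path file written by [write_wppin()].
#' @param aspect aspect label to attach.
#' @return a `wppin`.
#' @export
read_wppin <- function(path, aspect = "BP") {
  tab <- utils::read.delim(path, header = FALSE,
                           colClasses = c("character", "character", "numeric"))
  names(tab) <- c("a", "b", "weight")
  wppin_from_weights(tab, aspect = aspect)
}

#' Topology summary of a PPI network
#'
#' @param net a [ppi_network][integrate_edge_lists] (or `wppin`).
#' @param source optional source name: restrict to edges contributed by
#'   that source before summarising.
#' @return data frame with `proteins`, `interactions`, `degree_max`,
#'   `degree_min`, `degree_average` (2 decimals).
#' @export
topology_summary <- function(net, source = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  edges <- net$edges
  if (!is.null(source)) {
    if (!source %in% colnames(net$sources)) stop("unknown source: ", source)
    edges <- edges[net$sources[, source], , drop = FALSE]
  }
  if (!nrow(edges)) stop("network (or source slice) has no edges")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  deg <- igraph::degree(g)
  data.frame(proteins = igraph::vcount(g),
             interactions = igraph::ecount(g),
             degree_max = max(deg),
             degree_min = min(deg),
             degree_average = round(mean(deg), 2))
}
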