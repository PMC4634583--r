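#' Gene Ontology DAG for a single aspect
#'
#' An `ontology_graph` holds the terms of one GO aspect (BP, CC or MF)
#' together with the child-to-parent `is_a` / `part_of` relations.  The
#' graph is validated to be a directed acyclic graph at construction;
#' obsolete terms must have been removed by the caller (the OBO reader
#' does this).
#'
#' @param terms character vector of term identifiers.
#' @param parents named list, one entry per term, each a character vector
#'   of parent term identifiers (empty for roots).
#' @param relations named list parallel to `parents`, each a character
#'   vector of relation kinds (`"is_a"` or `"part_of"`).
#' @param aspect one of `"BP"`, `"CC"`, `"MF"`.
#'
#' @return An object of class `ontology_graph` with elements `terms`,
#'   `parents`, `relations`, `children` (reverse index), `roots`,
#'   `aspect`, and a private memoisation environment.
#' @export
ontology_graph <- function(terms, parents, relations, aspect) {
  aspect <- match.arg(aspect, c("BP", "CC", "MF"))
  terms <- unique(as.character(terms))
  stopifnot(all(names(parents) %in% terms), all(names(relations) %in% terms))
  parents <- parents[terms]
  relations <- relations[terms]
  names(parents) <- names(relations) <- terms
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else as.character(p))
  relations <- lapply(relations, function(r) if (is.null(r)) character(0) else as.character(r))

  bad_rel <- setdiff(unique(unlist(relations)), c("is_a", "part_of"))
  if (length(bad_rel)) {
    stop("unsupported relation kind(s): ", paste(bad_rel, collapse = ", "))
  }
  missing_parents <- setdiff(unique(unlist(parents)), terms)
  if (length(missing_parents)) {
    stop("parent term(s) absent from term set: ",
         paste(missing_parents, collapse = ", "))
  }

  # acyclicity check on the child -> parent relation
  edge_child <- rep(terms, lengths(parents))
  edge_parent <- unlist(parents, use.names = FALSE)
  if (length(edge_child)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edge_child, to = edge_parent,
                 stringsAsFactors = FALSE),
      directed = TRUE, vertices = terms)
    if (!igraph::is_dag(g)) {
      cyc <- igraph::feedback_arc_set(g)
      ends <- igraph::ends(g, cyc)
      stop("ontology relations contain a directed cycle (e.g. through edge ",
           ends[1, 1], " -> ", ends[1, 2], ")")
    }
  }

  children <- lapply(terms, function(t) character(0))
  names(children) <- terms
  if (length(edge_child)) {
    sp <- split(edge_child, edge_parent)
    children[names(sp)] <- lapply(sp, unique)
  }

  structure(
    list(terms = terms,
         parents = parents,
         relations = relations,
         children = children,
         roots = terms[lengths(parents) == 0L],
         aspect = aspect,
         cache = new.env(parent = emptyenv())),
    class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph (%s): %d terms, %d relations, %d root(s)\n",
              x$aspect, length(x$terms), sum(lengths(x$parents)),
              length(x$roots)))
  invisible(x)
}

#' Read an OBO ontology file
#'
#' Parses OBO 1.2/1.4 `[Term]` stanzas into one [ontology_graph] per GO
#' aspect.  Obsolete terms are dropped; only `is_a` and
#' `relationship: part_of` edges are retained, and any other relationship
#' kinds are skipped with a message reporting how many were ignored.
#' Cross-aspect parent relations (rare in GO, absent from fixtures) are
#' dropped so that each aspect is a self-contained DAG.
#'
#' @param path path to an OBO file.
#' @return Named list of [ontology_graph] objects keyed by aspect
#'   (`BP`, `CC`, `MF`); only aspects present in the file appear.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in OBO file: ", path)
  bounds <- c(starts, length(lines) + 1L)

  ids <- character(0); namespaces <- character(0)
  parent_list <- list(); rel_list <- list()
  obsolete <- character(0); skipped_rel <- 0L

  ns_map <- c(biological_process = "BP", cellular_component = "CC",
              molecular_function = "MF")

  for (k in seq_along(starts)) {
    if (lines[starts[k]] != "[Term]") next
    blk <- lines[(starts[k] + 1L):(bounds[k + 1L] - 1L)]
    blk <- blk[nzchar(blk)]
    get1 <- function(tag) {
      v <- sub(paste0("^", tag, ": *"), "", grep(paste0("^", tag, ": "), blk, value = TRUE))
      if (length(v)) v[[1]] else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) next
    if (identical(get1("is_obsolete"), "true")) {
      obsolete <- c(obsolete, id)
      next
    }
    ns <- ns_map[get1("namespace")]
    isa <- sub(" !.*$", "", sub("^is_a: *", "", grep("^is_a: ", blk, value = TRUE)))
    rel_lines <- sub("^relationship: *", "", grep("^relationship: ", blk, value = TRUE))
    rel_lines <- sub(" !.*$", "", rel_lines)
    rel_kind <- sub(" .*$", "", rel_lines)
    rel_target <- sub("^[^ ]+ +", "", rel_lines)
    keep <- rel_kind == "part_of"
    skipped_rel <- skipped_rel + sum(!keep)

    ids <- c(ids, id)
    namespaces <- c(namespaces, if (is.na(ns)) NA_character_ else unname(ns))
    parent_list[[id]] <- c(isa, rel_target[keep])
    rel_list[[id]] <- c(rep("is_a", length(isa)), rep("part_of", sum(keep)))
  }
  if (skipped_rel > 0L) {
    message("read_obo: skipped ", skipped_rel,
            " relationship(s) of unsupported kinds")
  }
  if (anyDuplicated(ids)) stop("duplicate term ids in OBO file")
  names(namespaces) <- ids

  out <- list()
  for (asp in c("BP", "CC", "MF")) {
    asp_ids <- ids[!is.na(namespaces) & namespaces == asp]
    if (!length(asp_ids)) next
    keep_set <- setdiff(asp_ids, obsolete)
    p <- lapply(parent_list[keep_set], function(pp) {
      pp[pp %in% keep_set]  # drop obsolete / cross-aspect parents
    })
    r <- mapply(function(pp, rr) rr[pp %in% keep_set],
                parent_list[keep_set], rel_list[keep_set], SIMPLIFY = FALSE)
    out[[asp]] <- ontology_graph(keep_set, p, r, asp)
  }
  if (!length(out)) stop("no non-obsolete terms with a recognised namespace in ", path)
  out
}
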