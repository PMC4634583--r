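#' @title Graph-based (Wang) term and gene semantic similarity
#' @description
#' The similarity of two GO terms is computed from their ancestor
#' closures: each ancestor `t` of a focal term `A` carries a
#' contribution score (s-value) defined recursively as
#' `S_A(A) = 1` and `S_A(t) = max over children t' of t within the
#' closure of w(t' -> t) * S_A(t')`, where `w` is the contribution
#' factor of the relation kind on the edge (0.8 for `is_a`, 0.6 for
#' `part_of` by default).  The semantic value `SV(A)` is the sum of all
#' s-values, and
#' `sim(A, B) = sum over shared closure terms of (S_A(t) + S_B(t)) / (SV(A) + SV(B))`.
#' @name semsim
NULL

default_relation_factors <- function() c(is_a = 0.8, part_of = 0.6)

check_relation_factors <- function(factors) {
  if (is.null(names(factors)) ||
      !all(c("is_a", "part_of") %in% names(factors))) {
    stop("relation factors must be named with 'is_a' and 'part_of'")
  }
  if (any(factors <= 0) || any(factors >= 1)) {
    stop("relation factors must lie strictly between 0 and 1")
  }
  factors
}

#' Ancestor closure and contribution scores of a term
#'
#' Computes the set of ancestors of `term` (including itself), the
#' s-value of every closure member under the max-of-weighted-children
#' recursion, and the semantic value (their sum).  Results are memoised
#' inside the graph object.
#'
#' @param term a term identifier present in `graph`.
#' @param graph an [ontology_graph].
#' @param factors named numeric of relation contribution factors;
#'   defaults to `c(is_a = 0.8, part_of = 0.6)`.
#' @return list with `term`, `members` (character), `s_values` (named
#'   numeric over `members`), `semantic_value`.
#' @export
term_closure <- function(term, graph, factors = default_relation_factors()) {
  stopifnot(inherits(graph, "ontology_graph"))
  factors <- check_relation_factors(factors)
  if (!term %in% graph$terms) {
    stop("term not in ontology graph: ", term)
  }
  key <- paste0("cl|", term, "|", paste(names(factors), factors,
                                        sep = "=", collapse = ","))
  hit <- graph$cache[[key]]
  if (!is.null(hit)) return(hit)

  # collect the ancestor closure by upward traversal
  members <- character(0)
  queue <- term
  while (length(queue)) {
    t0 <- queue[[1]]; queue <- queue[-1]
    if (t0 %in% members) next
    members <- c(members, t0)
    queue <- c(queue, graph$parents[[t0]])
  }

  # s-values: process members so every child is finished before its
  # parents (order by decreasing distance-from-focal is implied by
  # repeated relaxation over the closure's topological order)
  s <- stats::setNames(rep(NA_real_, length(members)), members)
  s[[term]] <- 1
  remaining <- setdiff(members, term)
  while (length(remaining)) {
    progressed <- FALSE
    for (t0 in remaining) {
      ch <- intersect(graph$children[[t0]], members)
      if (any(is.na(s[ch]))) next  # a closure child not yet resolved
      contrib <- vapply(ch, function(c0) {
        idx <- which(graph$parents[[c0]] == t0)
        w <- max(factors[graph$relations[[c0]][idx]])
        w * s[[c0]]
      }, numeric(1))
      s[[t0]] <- max(contrib)
      remaining <- setdiff(remaining, t0)
      progressed <- TRUE
    }
    if (!progressed) stop("cycle detected while resolving s-values")
  }

  out <- list(term = term, members = members, s_values = s,
              semantic_value = sum(s))
  graph$cache[[key]] <- out
  out
}

#' Semantic similarity of two GO terms
#'
#' @inheritParams term_closure
#' @param a,b term identifiers in the same aspect graph.
#' @return a score in (0, 1]; 1 exactly when `a == b`.
#' @export
term_similarity <- function(a, b, graph,
                            factors = default_relation_factors()) {
  ca <- term_closure(a, graph, factors)
  cb <- term_closure(b, graph, factors)
  shared <- intersect(ca$members, cb$members)
  if (!length(shared)) return(0)
  sum(ca$s_values[shared] + cb$s_values[shared]) /
    (ca$semantic_value + cb$semantic_value)
}

#' Semantic similarity of two genes
#'
#' Aggregates the term-by-term similarity matrix of the two genes'
#' annotation sets with the best-match average (default) or the maximum.
#' A gene with no annotation in the graph's aspect has no defined
#' similarity: the result is `NA_real_` ("missing"), never 0, so that
#' downstream consumers can distinguish absence of information from
#' functional dissimilarity.
#'
#' @param g1,g2 gene identifiers.
#' @param annotations an [annotation_map] for the same aspect as `graph`.
#' @param graph an [ontology_graph].
#' @param combine `"BMA"` (best-match average, default) or `"max"`.
#' @inheritParams term_closure
#' @return numeric score in \[0, 1\], or `NA_real_` when either gene is
#'   unannotated in this aspect.
#' @export
gene_similarity <- function(g1, g2, annotations, graph,
                            combine = c("BMA", "max"),
                            factors = default_relation_factors()) {
  combine <- match.arg(combine)
  stopifnot(inherits(annotations, "annotation_map"))
  if (annotations$aspect != graph$aspect) {
    stop("annotation map aspect (", annotations$aspect,
         ") does not match ontology aspect (", graph$aspect, ")")
  }
  t1 <- annotations$gene2terms[[g1]]
  t2 <- annotations$gene2terms[[g2]]
  if (is.null(t1) || !length(t1) || is.null(t2) || !length(t2)) {
    return(NA_real_)
  }
  key <- paste0("gs|", combine, "|",
                paste(sort(c(g1, g2)), collapse = "\r"), "|",
                paste(factors, collapse = ","))
  hit <- graph$cache[[key]]
  if (!is.null(hit)) return(hit)

  m <- matrix(NA_real_, length(t1), length(t2))
  for (i in seq_along(t1)) {
    for (j in seq_along(t2)) {
      m[i, j] <- term_similarity(t1[[i]], t2[[j]], graph, factors)
    }
  }
  score <- if (combine == "max") {
    max(m)
  } else {
    (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (nrow(m) + ncol(m))
  }
  graph$cache[[key]] <- score
  score
}
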