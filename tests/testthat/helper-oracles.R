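# ---- tiny hand-built ontologies -------------------------------------

# root R with two is_a children A, B
toy_ontology3 <- function() {
  ontology_graph(
    c("GO:R", "GO:A", "GO:B"),
    list("GO:R" = character(0), "GO:A" = "GO:R", "GO:B" = "GO:R"),
    list("GO:R" = character(0), "GO:A" = "is_a", "GO:B" = "is_a"),
    aspect = "BP")
}

# chain R <- A <- C (is_a twice)
chain_ontology3 <- function() {
  ontology_graph(
    c("GO:R", "GO:A", "GO:C"),
    list("GO:R" = character(0), "GO:A" = "GO:R", "GO:C" = "GO:A"),
    list("GO:R" = character(0), "GO:A" = "is_a", "GO:C" = "is_a"),
    aspect = "BP")
}

# random layered DAG with a single root
rand_ontology <- function(n_terms, seed, part_of_frac = 0.3,
                          aspect = "BP") {
  set.seed(seed)
  ids <- sprintf("GO:T%03d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  relations <- parents
  for (i in seq_along(ids)) {
    parents[[i]] <- character(0); relations[[i]] <- character(0)
    if (i == 1L) next
    k <- sample(1:min(2L, i - 1L), 1)
    p <- sample(ids[seq_len(i - 1L)], k)
    parents[[i]] <- p
    relations[[i]] <- ifelse(stats::runif(k) < part_of_frac,
                             "part_of", "is_a")
  }
  ontology_graph(ids, parents, relations, aspect)
}

# ---- brute-force semantic-similarity oracle -------------------------
# s-value of every ancestor by explicit enumeration of all root-ward
# paths: max over paths focal -> t of the product of relation factors.
oracle_closure <- function(term, graph,
                           factors = c(is_a = 0.8, part_of = 0.6)) {
  best <- new.env(parent = emptyenv())
  walk <- function(cur, val) {
    prev <- best[[cur]]
    if (is.null(prev) || val > prev) best[[cur]] <- val
    p <- graph$parents[[cur]]; r <- graph$relations[[cur]]
    for (k in seq_along(p)) walk(p[k], val * factors[[r[k]]])
  }
  walk(term, 1)
  s <- unlist(as.list(best))
  list(members = names(s), s_values = s, semantic_value = sum(s))
}

oracle_term_similarity <- function(a, b, graph,
                                   factors = c(is_a = 0.8, part_of = 0.6)) {
  ca <- oracle_closure(a, graph, factors)
  cb <- oracle_closure(b, graph, factors)
  shared <- intersect(ca$members, cb$members)
  if (!length(shared)) return(0)
  sum(ca$s_values[shared] + cb$s_values[shared]) /
    (ca$semantic_value + cb$semantic_value)
}

# ---- weighted-network builders --------------------------------------

wppin_from_edges <- function(a, b, w, aspect = "BP") {
  wppin_from_weights(data.frame(a = a, b = b, weight = w,
                                stringsAsFactors = FALSE),
                     aspect = aspect)
}

# random connected weighted graph: spanning tree + extra edges
rand_wppin <- function(n, seed, extra = n) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  a <- character(0); b <- character(0)
  for (i in 2:n) {                       # random tree keeps it connected
    a <- c(a, nodes[sample(i - 1L, 1)]); b <- c(b, nodes[i])
  }
  for (k in seq_len(extra)) {
    pair <- sample(nodes, 2)
    a <- c(a, pair[1]); b <- c(b, pair[2])
  }
  ed <- data.frame(a = pmin(a, b), b = pmax(a, b))
  ed <- unique(ed[ed$a != ed$b, ])
  ed$weight <- stats::runif(nrow(ed), 0.05, 1)
  wppin_from_weights(ed)
}

# ---- exhaustive minimum-hop max-product oracle ----------------------
# enumerate every minimum-hop path via DFS constrained to geodesics
# (each step must reduce the remaining hop distance to the target)
oracle_best_product <- function(net, g1, g2) {
  if (identical(g1, g2)) return(list(score = 1, hops = 0L))
  keep <- which(net$traversable)
  g <- igraph::graph_from_data_frame(net$edges[keep, , drop = FALSE],
                                     directed = FALSE,
                                     vertices = net$nodes)
  d_to_t <- igraph::distances(g, v = g2)[1, ]
  dst <- d_to_t[[g1]]
  if (!is.finite(dst)) return(list(score = 0, hops = NA_integer_))
  adj <- net$adjacency
  t_idx <- adj$index[[g2]]
  best <- -Inf
  rec <- function(u, depth, val) {
    if (u == t_idx) {
      if (depth == dst) best <<- max(best, val)
      return()
    }
    nb <- adj$neighbors[[u]]; ww <- adj$weights[[u]]
    for (k in seq_along(nb)) {
      if (d_to_t[[net$nodes[nb[k]]]] == dst - depth - 1) {
        rec(nb[k], depth + 1L, val * ww[k])
      }
    }
  }
  rec(adj$index[[g1]], 0L, 1)
  list(score = best, hops = as.integer(dst))
}
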