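#' Path search configuration
#'
#' @param max_hops optional positive integer cap on path length; pairs
#'   whose minimum-hop distance exceeds it score 0 and are flagged
#'   `capped`.  Default `Inf` (no cap).
#' @param score_rule `"product"` (default): the score of a path is the
#'   product of its edge weights, as in the pair-score definition; or
#'   `"geometric_mean"`: that product normalised as its n-th root,
#'   where n is the hop count.
#' @return object of class `path_search_config`.
#' @export
path_search_config <- function(max_hops = Inf,
                               score_rule = c("product", "geometric_mean")) {
  score_rule <- match.arg(score_rule)
  if (!is.infinite(max_hops)) {
    max_hops <- as.integer(max_hops)
    if (is.na(max_hops) || max_hops < 1L) stop("max_hops must be >= 1")
  }
  structure(list(max_hops = max_hops, score_rule = score_rule),
            class = "path_search_config")
}

# lexicographic order on equal-length node sequences
path_less <- function(p, q) {
  for (k in seq_along(p)) {
    if (p[k] < q[k]) return(TRUE)
    if (p[k] > q[k]) return(FALSE)
  }
  FALSE
}

apply_score_rule <- function(raw, hops, score_rule) {
  if (score_rule == "product" || is.na(hops) || hops == 0L || raw <= 0) {
    return(raw)
  }
  raw^(1 / hops)
}

#' Gene-pair functional similarity: best product over minimum-hop paths
#'
#' The functional similarity of two genes is the maximum accumulated
#' edge-weight product over all minimum-hop shortest paths between them
#' in the weighted network.  The search is a weighted breadth-first
#' search: the BFS tree is grown layer by layer and pruned by dominance
#' — per node and per layer only the best accumulated product (with
#' the lexicographically smallest witness path as tie-break) is kept,
#' which provably never discards an optimal path since every prefix of
#' a minimum-hop path is itself minimum-hop.
#'
#' A gene compared with itself scores exactly 1 (path length 0);
#' disconnected pairs score 0.
#'
#' @param g1,g2 gene ids; both must be nodes of `net` (absence is an
#'   error — callers handle out-of-network genes via the set-level
#'   exclusion counts).
#' @param net a [wppin][weight_network].
#' @param cfg a [path_search_config()].
#' @return object of class `gene_pair_score`: `gene_i`, `gene_j`,
#'   `score`, `path_length` (`NA` when disconnected), `path` (witness
#'   node sequence, `NULL` when disconnected), `capped`.
#' @export
shortest_path_best_product <- function(g1, g2, net,
                                       cfg = path_search_config()) {
  stopifnot(inherits(net, "wppin"), inherits(cfg, "path_search_config"))
  adj <- net$adjacency
  if (!g1 %in% names(adj$index)) stop("gene not in network: ", g1)
  if (!g2 %in% names(adj$index)) stop("gene not in network: ", g2)

  res <- list(gene_i = g1, gene_j = g2, capped = FALSE)
  if (identical(g1, g2)) {
    res$score <- 1; res$path_length <- 0L; res$path <- g1
    class(res) <- "gene_pair_score"
    return(res)
  }

  s <- adj$index[[g1]]; t <- adj$index[[g2]]
  n <- length(net$nodes)
  depth <- rep(NA_integer_, n)
  prod_ <- rep(NA_real_, n)
  paths <- vector("list", n)
  depth[s] <- 0L; prod_[s] <- 1; paths[[s]] <- s
  frontier <- s; d <- 0L; found <- FALSE

  while (length(frontier) && !found && d < cfg$max_hops) {
    nxt <- integer(0)
    for (u in frontier) {
      nb <- adj$neighbors[[u]]; ww <- adj$weights[[u]]
      for (k in seq_along(nb)) {
        v <- nb[k]
        if (!is.na(depth[v]) && depth[v] <= d) next  # seen earlier layer
        cand <- prod_[u] * ww[k]
        cand_path <- c(paths[[u]], v)
        if (is.na(depth[v])) {
          depth[v] <- d + 1L; prod_[v] <- cand; paths[[v]] <- cand_path
          nxt <- c(nxt, v)
        } else if (cand > prod_[v] ||
                   (cand == prod_[v] && path_less(cand_path, paths[[v]]))) {
          prod_[v] <- cand; paths[[v]] <- cand_path
        }
      }
    }
    d <- d + 1L
    frontier <- nxt
    if (!is.na(depth[t])) found <- TRUE
  }

  if (!found) {
    res$score <- 0
    res$path_length <- NA_integer_
    res$path <- NULL
    res$capped <- length(frontier) > 0L  # stopped by the cap, not exhaustion
  } else {
    res$path_length <- depth[t]
    res$score <- apply_score_rule(prod_[t], depth[t], cfg$score_rule)
    res$path <- net$nodes[paths[[t]]]
  }
  class(res) <- "gene_pair_score"
  res
}

#' @export
print.gene_pair_score <- function(x, ...) {
  cat(sprintf("gene_pair_score: %s ~ %s  score=%.6f  hops=%s\n",
              x$gene_i, x$gene_j, x$score,
              ifelse(is.na(x$path_length), "disconnected", x$path_length)))
  invisible(x)
}

# single-source layered BFS: best min-hop product from `start` (integer
# node index) to every node.  Cached per network; witness paths are not
# tracked here (the single-pair search does that).
best_products_from <- function(net, start, max_hops = Inf) {
  key <- paste0("sp|", start, "|", max_hops)
  hit <- net$path_cache[[key]]
  if (!is.null(hit)) return(hit)
  adj <- net$adjacency
  n <- length(net$nodes)
  depth <- rep(NA_integer_, n); prod_ <- rep(0, n)
  depth[start] <- 0L; prod_[start] <- 1
  frontier <- start; d <- 0L
  while (length(frontier) && d < max_hops) {
    layer_v <- integer(0); layer_s <- numeric(0)
    for (u in frontier) {
      nb <- adj$neighbors[[u]]
      if (!length(nb)) next
      unseen <- is.na(depth[nb])
      if (!any(unseen)) next
      layer_v <- c(layer_v, nb[unseen])
      layer_s <- c(layer_s, prod_[u] * adj$weights[[u]][unseen])
    }
    if (!length(layer_v)) break
    best <- vapply(split(layer_s, layer_v), max, numeric(1))
    vids <- as.integer(names(best))
    depth[vids] <- d + 1L
    prod_[vids] <- unname(best)
    frontier <- vids
    d <- d + 1L
  }
  out <- list(product = prod_, depth = depth)
  net$path_cache[[key]] <- out
  out
}

#' All-pairs gene similarity matrix between two gene sets
#'
#' @param set1,set2 character vectors of gene ids, already restricted to
#'   genes present in `net`.
#' @param net a [wppin][weight_network].
#' @param cfg a [path_search_config()].
#' @return numeric matrix of shape `length(set1) x length(set2)` with
#'   dimnames, entries as from [shortest_path_best_product()].
#' @export
all_pairs_gene_scores <- function(set1, set2, net,
                                  cfg = path_search_config()) {
  stopifnot(inherits(net, "wppin"))
  set1 <- as.character(set1); set2 <- as.character(set2)
  m <- matrix(numeric(0), length(set1), length(set2),
              dimnames = list(set1, set2))
  if (!length(set1) || !length(set2)) return(m)
  idx <- net$adjacency$index
  miss <- setdiff(c(set1, set2), names(idx))
  if (length(miss)) stop("gene(s) not in network: ", paste(miss, collapse = ", "))
  for (i in seq_along(set1)) {
    sp <- best_products_from(net, idx[[set1[i]]], cfg$max_hops)
    j_idx <- idx[set2]
    raw <- sp$product[j_idx]
    hops <- sp$depth[j_idx]
    m[i, ] <- mapply(apply_score_rule, raw, hops,
                     MoreArgs = list(score_rule = cfg$score_rule))
  }
  m
}
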