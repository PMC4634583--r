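#' Read a miRNA -> target-gene table
#'
#' Accepts the 2-column TSV dialect (mirna id, target gene id); rows for
#' the same miRNA are collected and deduplicated, mirroring a union of
#' target predictions from several tools with redundancies removed.
#'
#' @param path file path.
#' @param header whether the first row is a header (default FALSE).
#' @param normalize_ids normalise target gene ids (default TRUE).
#' @return named list: miRNA id -> character vector of target genes.
#' @export
read_target_sets <- function(path, header = FALSE, normalize_ids = TRUE) {
  tab <- utils::read.delim(path, header = header, colClasses = "character")
  if (ncol(tab) < 2L) stop("target table needs >= 2 columns: ", path)
  genes <- tab[[2]]
  if (normalize_ids) genes <- normalize_gene_ids(genes)
  lapply(split(genes, tab[[1]]), unique)
}

#' Functional similarity of two target gene sets (modified BMA)
#'
#' Aggregates the gene-pair score matrix of the two miRNAs' target sets
#' into one score:
#' `FS = (sum of row maxima + sum of column maxima) / ((m - m') + (n - n'))`,
#' where m, n are the target-set sizes and m', n' count target genes
#' absent from the weighted network.  Excluded genes contribute to
#' neither numerator nor denominator.
#'
#' When both effective (in-network) sets are empty the score is
#' undefined (`NA`, status `"undefined"`), because the denominator is
#' zero; when exactly one is empty the score is 0 with a warning, since
#' no best match exists for any gene.
#'
#' @param targets_i,targets_j character vectors of target gene ids (the
#'   raw, deduplicated sets).
#' @param net a [wppin][weight_network].
#' @param cfg a [path_search_config()].
#' @return object of class `target_set_similarity`: `score`, `m`, `n`,
#'   `m_excluded`, `n_excluded`, `status` (`"ok"` or `"undefined"`).
#' @export
target_set_similarity <- function(targets_i, targets_j, net,
                                  cfg = path_search_config()) {
  stopifnot(inherits(net, "wppin"))
  targets_i <- unique(as.character(targets_i))
  targets_j <- unique(as.character(targets_j))
  in_i <- intersect(targets_i, net$nodes)
  in_j <- intersect(targets_j, net$nodes)
  out <- list(m = length(targets_i), n = length(targets_j),
              m_excluded = length(targets_i) - length(in_i),
              n_excluded = length(targets_j) - length(in_j))

  if (!length(in_i) && !length(in_j)) {
    out$score <- NA_real_
    out$status <- "undefined"
  } else if (!length(in_i) || !length(in_j)) {
    warning("one effective target set is empty; score degenerates to 0")
    out$score <- 0
    out$status <- "ok"
  } else {
    f <- all_pairs_gene_scores(in_i, in_j, net, cfg)
    out$score <- (sum(apply(f, 1, max)) + sum(apply(f, 2, max))) /
      (nrow(f) + ncol(f))
    out$status <- "ok"
  }
  class(out) <- "target_set_similarity"
  out
}

#' @export
print.target_set_similarity <- function(x, ...) {
  cat(sprintf(
    "target_set_similarity: score=%s  m=%d (%d excluded)  n=%d (%d excluded)  [%s]\n",
    ifelse(is.na(x$score), "NA", sprintf("%.6f", x$score)),
    x$m, x$m_excluded, x$n, x$n_excluded, x$status))
  invisible(x)
}

#' All-pairs miRNA functional similarity matrix
#'
#' @param sets named list of target gene sets (miRNA id -> genes);
#'   needs at least 2 miRNAs.
#' @param net a [wppin][weight_network].
#' @param cfg a [path_search_config()].
#' @return symmetric numeric matrix with unit diagonal and miRNA ids as
#'   dimnames; undefined pairs are `NA`.  The aspect is attached as the
#'   `"aspect"` attribute.
#' @export
similarity_matrix <- function(sets, net, cfg = path_search_config()) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (length(sets) < 2L) stop("need >= 2 miRNAs for a similarity matrix")
  ids <- names(sets)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      s <- suppressWarnings(
        target_set_similarity(sets[[i]], sets[[j]], net, cfg))
      m[i, j] <- m[j, i] <- s$score
    }
  }
  attr(m, "aspect") <- net$aspect
  m
}

#' Write a similarity matrix as square TSV
#'
#' Header row and first column carry the miRNA ids; undefined entries
#' are serialized as `NA`, never 0.
#'
#' @param m matrix from [similarity_matrix()].
#' @param path output file.
#' @param digits decimal places (default 6).
#' @export
write_similarity_matrix <- function(m, path, digits = 6) {
  out <- format(round(m, digits), nsmall = digits, trim = TRUE)
  out[is.na(m)] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a square similarity matrix written by [write_similarity_matrix()]
#'
#' @param path TSV file with miRNA ids as header row and first column.
#' @return numeric matrix with dimnames.
#' @export
read_similarity_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  as.matrix(tab)
}

#' Jaccard similarity of two raw target sets
#'
#' The baseline set-overlap measure: |intersection| / |union| of the raw
#' target sets, ignoring network membership.  For plant miRNAs, whose
#' target sets are small and rarely intersect, this baseline is mostly
#' zero — the motivation for the network-based score.
#'
#' @param targets_i,targets_j character vectors of target gene ids.
#' @return score in \[0, 1\].
#' @export
jaccard_similarity <- function(targets_i, targets_j) {
  targets_i <- unique(as.character(targets_i))
  targets_j <- unique(as.character(targets_j))
  u <- union(targets_i, targets_j)
  if (!length(u)) stop("both target sets are empty; Jaccard undefined")
  length(intersect(targets_i, targets_j)) / length(u)
}
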