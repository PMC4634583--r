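#' Canonical unordered pair key
#'
#' @param a,b vectors of ids (recycled).
#' @return character vector of keys, independent of argument order.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

all_pair_keys <- function(ids) {
  ids <- sort(unique(ids))
  if (length(ids) < 2L) return(character(0))
  cmb <- utils::combn(ids, 2L)
  pair_key(cmb[1, ], cmb[2, ])
}

#' Read miRNA genome coordinates
#'
#' Accepts a 4/5-column BED-like TSV (`mirna`, `chrom`, `start`, `end`
#' [, `strand`]; 1-based inclusive coordinates) or a GFF3 file, in which
#' case the `ID` (or `Name`) attribute supplies the miRNA id and the
#' GFF coordinates are already 1-based inclusive.  GFF3 parsing uses
#' rtracklayer when available.
#'
#' @param path file path (`.gff`/`.gff3` triggers GFF parsing).
#' @param header whether the TSV has a header row (default FALSE).
#' @return data frame with columns `mirna`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_mirna_coords <- function(path, header = FALSE) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- rtracklayer::import(path)
      md <- as.data.frame(gr)
      id <- if ("ID" %in% names(md)) md$ID else md$Name
      return(data.frame(mirna = as.character(id),
                        chrom = as.character(md$seqnames),
                        start = md$start, end = md$end,
                        strand = as.character(md$strand),
                        stringsAsFactors = FALSE))
    }
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 9L)) stop("malformed GFF3: ", path)
    attr9 <- vapply(f, `[[`, character(1), 9L)
    id <- sub("^.*(?:^|;)ID=([^;]+).*$", "\\1", attr9)
    noid <- !grepl("ID=", attr9)
    id[noid] <- sub("^.*(?:^|;)Name=([^;]+).*$", "\\1", attr9[noid])
    return(data.frame(
      mirna = id,
      chrom = vapply(f, `[[`, character(1), 1L),
      start = as.integer(vapply(f, `[[`, character(1), 4L)),
      end = as.integer(vapply(f, `[[`, character(1), 5L)),
      strand = vapply(f, `[[`, character(1), 7L),
      stringsAsFactors = FALSE))
  }
  tab <- utils::read.delim(path, header = header, colClasses = "character")
  if (ncol(tab) < 4L) stop("coordinate table needs >= 4 columns")
  data.frame(mirna = tab[[1]], chrom = tab[[2]],
             start = as.integer(tab[[3]]), end = as.integer(tab[[4]]),
             strand = if (ncol(tab) >= 5L) tab[[5]] else "*",
             stringsAsFactors = FALSE)
}

#' Assign miRNAs to genomic clusters
#'
#' Single-linkage chaining of miRNA genes along each chromosome:
#' consecutive genes whose end-to-start gap is at most `max_gap`
#' (default 10 kb, the conventional inter-miRNA clustering distance)
#' share a cluster.  Singleton clusters are dropped.
#'
#' @param coords data frame as from [read_mirna_coords()]; duplicate
#'   miRNA ids are an error.
#' @param max_gap maximum gap in bp (default 10000).
#' @return named character vector: miRNA id -> cluster id, covering
#'   only clustered (non-singleton) miRNAs.
#' @export
assign_genomic_clusters <- function(coords, max_gap = 10000) {
  stopifnot(all(c("mirna", "chrom", "start", "end") %in% names(coords)))
  if (anyDuplicated(coords$mirna)) {
    stop("duplicate miRNA id(s) in coordinates: ",
         paste(unique(coords$mirna[duplicated(coords$mirna)]), collapse = ", "))
  }
  out <- character(0)
  for (chr in unique(coords$chrom)) {
    sub <- coords[coords$chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (nrow(sub) == 0L) next
    cluster_no <- 1L
    assign <- integer(nrow(sub))
    assign[1] <- cluster_no
    if (nrow(sub) > 1L) {
      for (i in 2:nrow(sub)) {
        gap <- sub$start[i] - sub$end[i - 1L]
        if (gap > max_gap) cluster_no <- cluster_no + 1L
        assign[i] <- cluster_no
      }
    }
    tab <- table(assign)
    keep <- assign %in% as.integer(names(tab)[tab >= 2L])
    if (any(keep)) {
      lab <- stats::setNames(paste0(chr, "_c", assign[keep]),
                             sub$mirna[keep])
      out <- c(out, lab)
    }
  }
  out
}

#' Partition miRNA pairs into intra-group, inter-group and random
#'
#' For a chosen grouping (family or cluster), pairs whose members share
#' a group label are intra, pairs whose members carry different labels
#' of that grouping are inter, and the random class is sampled from the
#' remaining pairs — excluding intra and inter pairs of *both*
#' groupings, so random pairs are unrelated by family and by genomic
#' cluster alike.
#'
#' @param mirnas character vector of miRNA ids under study.
#' @param families named character vector miRNA -> family label (absent
#'   or `NA` = no family).
#' @param clusters named character vector miRNA -> cluster label, e.g.
#'   from [assign_genomic_clusters()].
#' @param kind `"family"` or `"cluster"`: which grouping defines the
#'   intra/inter classes.
#' @param n_random number of random pairs to draw.
#' @param seed integer seed making the random draw reproducible.
#' @return object of class `pair_partition`: `intra`, `inter`, `random`
#'   (character vectors of [pair_key()]s) and `kind`.
#' @export
partition_pairs <- function(mirnas, families, clusters,
                            kind = c("family", "cluster"),
                            n_random, seed = 1L) {
  kind <- match.arg(kind)
  mirnas <- sort(unique(as.character(mirnas)))
  grp <- if (kind == "family") families else clusters

  classify <- function(map) {
    la <- map[pair_a]; lb <- map[pair_b]
    both <- !is.na(la) & !is.na(lb)
    list(intra = both & la == lb, inter = both & la != lb)
  }
  cmb <- utils::combn(mirnas, 2L)
  pair_a <- cmb[1, ]; pair_b <- cmb[2, ]
  keys <- pair_key(pair_a, pair_b)

  main <- classify(grp)
  if (!any(main$intra)) {
    stop("no multi-member ", kind, " groups among the supplied miRNAs")
  }
  fam_cls <- classify(families)
  clu_cls <- classify(clusters)
  eligible <- !(fam_cls$intra | fam_cls$inter | clu_cls$intra | clu_cls$inter)

  if (n_random > sum(eligible)) {
    stop("n_random (", n_random, ") exceeds the ", sum(eligible),
         " eligible random pairs")
  }
  rnd <- with_local_seed(seed, sample(keys[eligible], n_random))
  structure(list(intra = keys[main$intra], inter = keys[main$inter],
                 random = rnd, kind = kind),
            class = "pair_partition")
}

#' @export
print.pair_partition <- function(x, ...) {
  cat(sprintf("pair_partition (%s): %d intra, %d inter, %d random\n",
              x$kind, length(x$intra), length(x$inter), length(x$random)))
  invisible(x)
}

#' Rank-based comparison of score groups
#'
#' Runs the Kruskal-Wallis test across all groups (requires >= 3) and,
#' taking the first group as the reference (conventionally the
#' intra-group scores), one-sided Wilcoxon rank-sum tests of
#' reference > other for every other group.  Exact p-values are used
#' when both samples have at most 20 untied observations, the
#' normal approximation with tie correction otherwise.
#'
#' @param scores named list of numeric vectors, one per group; each
#'   group needs >= 2 observations.
#' @return list with `kruskal` (`H`, `df`, `p`; `NULL` with < 3 groups)
#'   and `pairwise` (data frame: `comparison`, `W`, `p_one_sided`).
#' @export
group_comparison <- function(scores) {
  stopifnot(is.list(scores), !is.null(names(scores)), length(scores) >= 2L)
  if (any(vapply(scores, length, integer(1)) < 2L)) {
    stop("every group needs >= 2 observations")
  }
  kw <- NULL
  if (length(scores) >= 3L) {
    k <- stats::kruskal.test(scores)
    kw <- list(H = unname(k$statistic), df = unname(k$parameter),
               p = k$p.value)
  }
  ref_name <- names(scores)[1]
  others <- names(scores)[-1]
  rows <- lapply(others, function(g) {
    x <- scores[[ref_name]]; y <- scores[[g]]
    exact <- length(x) <= 20L && length(y) <= 20L &&
      !anyDuplicated(c(x, y))
    wt <- stats::wilcox.test(x, y, alternative = "greater", exact = exact,
                             correct = !exact)
    data.frame(comparison = paste0(ref_name, ">", g),
               W = unname(wt$statistic), p_one_sided = wt$p.value,
               stringsAsFactors = FALSE)
  })
  list(kruskal = kw, pairwise = do.call(rbind, rows))
}

#' 1-positive-vs-99-negatives prioritization ROC
#'
#' For every positive pair, `negatives_per_positive` negative pairs are
#' drawn from the negative pool and the positive's score is ranked
#' within the resulting list (descending scores; ties get the mid-rank,
#' so uninformative all-equal scores yield AUC 0.5).  The true positive
#' rate at rank threshold t is the fraction of positives ranked at or
#' above t; the false positive rate is computed analogously from the
#' pooled negative ranks.  The AUC is the trapezoidal area over the
#' thresholds 0 .. list size.
#'
#' @param positives character vector of positive [pair_key()]s.
#' @param negative_pool character vector of candidate negative pair
#'   keys (the caller applies the exclusion rules — e.g. no same-family,
#'   same-cluster or same-stress pairs).
#' @param scores named numeric vector: pair key -> similarity score,
#'   covering all positives and the pool.
#' @param negatives_per_positive number of negatives per list
#'   (default 99, giving lists of 100).
#' @param seed integer seed for the negative sampling.
#' @return object of class `ranking_experiment`: `ranks` (positive rank
#'   per list), `roc` (data frame `threshold`, `tpr`, `fpr`), `auc`,
#'   `list_size`.
#' @export
roc_prioritization <- function(positives, negative_pool, scores,
                               negatives_per_positive = 99L, seed = 1L) {
  positives <- as.character(positives)
  negative_pool <- setdiff(as.character(negative_pool), positives)
  if (length(negative_pool) < negatives_per_positive) {
    stop("negative pool (", length(negative_pool),
         ") smaller than negatives_per_positive (",
         negatives_per_positive, ")")
  }
  need <- c(positives, negative_pool)
  miss <- need[!need %in% names(scores)]
  if (length(miss)) {
    stop("missing scores for ", length(miss), " pair(s), e.g. ", miss[[1]])
  }
  list_size <- negatives_per_positive + 1L

  lists <- with_local_seed(seed, lapply(positives, function(p) {
    sample(negative_pool, negatives_per_positive)
  }))
  pos_rank <- numeric(length(positives))
  neg_rank <- vector("list", length(positives))
  for (i in seq_along(positives)) {
    sc <- c(scores[[positives[i]]], unname(scores[lists[[i]]]))
    rk <- rank(-sc, ties.method = "average")
    pos_rank[i] <- rk[1]
    neg_rank[[i]] <- rk[-1]
  }
  neg_rank <- unlist(neg_rank)

  thr <- 0:list_size
  tpr <- vapply(thr, function(t) mean(pos_rank <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg_rank <= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  structure(list(ranks = pos_rank,
                 roc = data.frame(threshold = thr, tpr = tpr, fpr = fpr),
                 auc = auc, list_size = list_size),
            class = "ranking_experiment")
}

#' @export
print.ranking_experiment <- function(x, ...) {
  cat(sprintf("ranking_experiment: %d lists of %d, AUC = %.4f\n",
              length(x$ranks), x$list_size, x$auc))
  invisible(x)
}

#' Read a miRNA -> stress-label association table
#'
#' @param path 2-column TSV (mirna id, stress label); one row per
#'   association, a miRNA may carry several labels.
#' @param header whether the first row is a header.
#' @return named list: miRNA id -> character vector of stress labels.
#' @export
read_stress_table <- function(path, header = FALSE) {
  tab <- utils::read.delim(path, header = header, colClasses = "character")
  if (ncol(tab) < 2L) stop("stress table needs >= 2 columns: ", path)
  lapply(split(tab[[2]], tab[[1]]), unique)
}

#' Positive / negative test sets from stress associations
#'
#' Positives are all unordered miRNA pairs sharing at least one stress
#' label; each negative set is a same-sized sample (without
#' replacement) of pairs sharing no label.
#'
#' @param assoc named list miRNA -> stress labels (see
#'   [read_stress_table()]).
#' @param all_mirnas character vector of the miRNA universe from which
#'   pairs are formed.
#' @param n_negative_sets number of negative sets (default 50).
#' @param seed integer seed.
#' @return list with `positives` (pair keys) and `negative_sets` (list
#'   of pair-key vectors, each of length `length(positives)`).
#' @export
stress_pair_experiment <- function(assoc, all_mirnas,
                                   n_negative_sets = 50L, seed = 1L) {
  all_mirnas <- sort(unique(as.character(all_mirnas)))
  cmb <- utils::combn(all_mirnas, 2L)
  share <- mapply(function(a, b) {
    la <- assoc[[a]]; lb <- assoc[[b]]
    !is.null(la) && !is.null(lb) && length(intersect(la, lb)) > 0L
  }, cmb[1, ], cmb[2, ])
  keys <- pair_key(cmb[1, ], cmb[2, ])
  positives <- keys[share]
  if (!length(positives)) stop("no miRNA pair shares a stress label")
  pool <- keys[!share]
  if (length(pool) < length(positives)) {
    stop("only ", length(pool), " non-sharing pairs available for negative",
         " sets of size ", length(positives))
  }
  negative_sets <- with_local_seed(seed, lapply(seq_len(n_negative_sets),
    function(i) sample(pool, length(positives))))
  list(positives = positives, negative_sets = negative_sets)
}
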