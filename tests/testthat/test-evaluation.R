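test_that("genomic clustering follows the 10-kb single-linkage rule", {
  coords <- data.frame(
    mirna = c("m1", "m2", "m3", "m4"),
    chrom = c("Chr1", "Chr1", "Chr2", "Chr2"),
    start = c(1000, 6200, 1000, 20000),
    end = c(1120, 6320, 1120, 20120))
  cl <- assign_genomic_clusters(coords)
  # 5-kb gap clusters m1+m2; m3/m4 are 18.9 kb apart -> singletons
  expect_identical(unname(cl["m1"]), unname(cl["m2"]))
  expect_false("m3" %in% names(cl))
  expect_false("m4" %in% names(cl))

  # same positions on different chromosomes never cluster
  coords2 <- data.frame(mirna = c("a", "b"), chrom = c("Chr1", "Chr2"),
                        start = c(1000, 1000), end = c(1120, 1120))
  expect_length(assign_genomic_clusters(coords2), 0)

  # chaining: consecutive 9-kb gaps form one 3-member cluster even
  # though the ends are 18 kb apart
  coords3 <- data.frame(mirna = c("a", "b", "c"), chrom = "Chr1",
                        start = c(1000, 10120, 19240),
                        end = c(1120, 10240, 19360))
  cl3 <- assign_genomic_clusters(coords3)
  expect_length(unique(cl3), 1)
  expect_setequal(names(cl3), c("a", "b", "c"))
  # with a tighter gap the chain breaks
  cl3b <- assign_genomic_clusters(coords3, max_gap = 5000)
  expect_length(cl3b, 0)

  expect_error(assign_genomic_clusters(rbind(coords, coords[1, ])),
               "duplicate")
})

test_that("coordinate readers accept BED-like TSV and GFF3", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("m1\tChr1\t1000\t1120\t+", "m2\tChr1\t6200\t6320\t-"), f)
  tab <- read_mirna_coords(f)
  expect_identical(tab$mirna, c("m1", "m2"))
  expect_identical(tab$start, c(1000L, 6200L))

  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "Chr1\tfix\tmiRNA\t1000\t1120\t.\t+\t.\tID=m1;Name=m1",
               "Chr1\tfix\tmiRNA\t6200\t6320\t.\t-\t.\tID=m2"), g)
  tab2 <- read_mirna_coords(g)
  expect_setequal(tab2$mirna, c("m1", "m2"))
  expect_identical(sort(tab2$start), c(1000L, 6200L))
})

test_that("pair partitions: hand counts, determinism, and disjointness
          from all grouped pairs", {
  mirnas <- sprintf("m%02d", 1:10)
  families <- stats::setNames(c("F1", "F1", "F2", "F2"), mirnas[1:4])
  clusters <- stats::setNames(c("C1", "C1"), mirnas[5:6])
  part <- partition_pairs(mirnas, families, clusters, kind = "family",
                          n_random = 5, seed = 9)
  # 2 families of 2: 2 intra pairs, 2*2 inter pairs
  expect_length(part$intra, 2)
  expect_length(part$inter, 4)
  expect_setequal(part$intra, c(pair_key("m01", "m02"),
                                pair_key("m03", "m04")))
  # same seed twice -> identical random draw
  part2 <- partition_pairs(mirnas, families, clusters, kind = "family",
                           n_random = 5, seed = 9)
  expect_identical(part2$random, part$random)

  # random pairs avoid intra/inter pairs of both groupings: exhaustive
  # scan over every drawn pair
  forbidden <- c(part$intra, part$inter, pair_key("m05", "m06"))
  expect_length(intersect(part$random, forbidden), 0)
  grouped <- names(c(families, clusters))
  for (p in part$random) {
    ab <- strsplit(p, "|", fixed = TRUE)[[1]]
    expect_false(all(ab %in% names(families)))  # never two family members
    expect_false(all(ab %in% names(clusters)))
  }

  cl_part <- partition_pairs(mirnas, families, clusters, kind = "cluster",
                             n_random = 3, seed = 1)
  expect_identical(cl_part$intra, pair_key("m05", "m06"))
  expect_error(partition_pairs(mirnas, families,
                               stats::setNames("C1", "m05"),
                               kind = "cluster", n_random = 2),
               "no multi-member")
  expect_error(partition_pairs(mirnas, families, clusters,
                               kind = "family", n_random = 10000),
               "exceeds")
})

test_that("group comparison: identical groups give H = 0; the extreme
          3-vs-3 arrangement gives exact one-sided p = 0.05", {
  same <- list(intra = c(1, 2, 3), inter = c(1, 2, 3),
               random = c(1, 2, 3))
  res <- suppressWarnings(group_comparison(same))
  expect_equal(res$kruskal$H, 0)
  expect_equal(res$kruskal$df, 2)

  # exhaustive enumeration: the all-high arrangement is 1 of C(6,3)=20
  res2 <- group_comparison(list(intra = c(10, 11, 12),
                                other = c(1, 2, 3)))
  expect_null(res2$kruskal)
  expect_equal(res2$pairwise$p_one_sided, 1 / 20)
  expect_identical(res2$pairwise$comparison, "intra>other")

  expect_error(group_comparison(list(a = 1, b = c(1, 2))), ">= 2")
})

test_that("the Kruskal-Wallis H matches the textbook rank formula", {
  set.seed(17)
  groups <- list(a = rnorm(12), b = rnorm(15, 0.5), c = rnorm(9, 1))
  res <- group_comparison(groups)
  x <- unlist(groups); g <- rep(names(groups), lengths(groups))
  r <- rank(x); n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  # no ties in these draws, so no tie correction applies
  expect_equal(res$kruskal$H, h, tolerance = 1e-10)
  expect_equal(res$kruskal$p,
               stats::pchisq(h, df = 2, lower.tail = FALSE))
})

test_that("one-sided rank-sum p agrees with the large-sample normal
          approximation under ties", {
  set.seed(18)
  x <- round(rnorm(40, 1), 1); y <- round(rnorm(40), 1)  # forced ties
  res <- group_comparison(list(intra = x, random = y))
  ref <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                            correct = TRUE)
  expect_equal(res$pairwise$p_one_sided, ref$p.value)
})

test_that("prioritization ROC: perfect separation gives AUC 1, all-tied
          scores give AUC 0.5", {
  mir <- sprintf("m%02d", 1:30)
  keys <- utils::combn(mir, 2)
  keys <- pair_key(keys[1, ], keys[2, ])
  positives <- keys[1:5]
  pool <- setdiff(keys, positives)

  hi <- stats::setNames(c(rep(1, 5), rep(0.1, length(pool))),
                        c(positives, pool))
  r1 <- roc_prioritization(positives, pool, hi,
                           negatives_per_positive = 99, seed = 4)
  expect_equal(r1$auc, 1)
  expect_true(all(r1$ranks == 1))

  tied <- stats::setNames(rep(0.5, length(keys)), keys)
  r2 <- roc_prioritization(positives, pool, tied,
                           negatives_per_positive = 99, seed = 4)
  expect_equal(r2$auc, 0.5)
  expect_true(all(r2$ranks == 50.5))   # mid-rank of a 100-way tie

  expect_error(roc_prioritization(positives, pool[1:50], hi,
                                  negatives_per_positive = 99),
               "smaller")
})

test_that("the ROC AUC matches the Mann-Whitney identity
          P(pos > neg) + 0.5 P(tie) on overlapping score
          distributions", {
  mir <- sprintf("m%03d", 1:60)
  keys <- utils::combn(mir, 2)
  keys <- pair_key(keys[1, ], keys[2, ])
  set.seed(31)
  positives <- sample(keys, 40)
  pool <- setdiff(keys, positives)
  scores <- stats::setNames(numeric(length(keys)), keys)
  scores[positives] <- round(stats::rnorm(length(positives), 0.6, 0.25), 2)
  scores[pool] <- round(stats::rnorm(length(pool), 0.3, 0.25), 2)

  r <- roc_prioritization(positives, pool, scores,
                          negatives_per_positive = 99, seed = 5)
  # oracle: exhaustive pairwise comparison over the same negative
  # draws, reproduced through the documented seeding scheme
  set.seed(5)
  lists <- lapply(seq_along(positives), function(i) sample(pool, 99))
  u <- 0; n_cmp <- 0
  for (i in seq_along(positives)) {
    u <- u + sum(scores[positives[i]] > scores[lists[[i]]]) +
      0.5 * sum(scores[positives[i]] == scores[lists[[i]]])
    n_cmp <- n_cmp + 99
  }
  expect_lt(abs(r$auc - u / n_cmp), 1 / 100 + 1e-9)
  expect_gt(r$auc, 0.5)
})

test_that("stress pair construction: hand count, label disjointness of
          negatives, and seed reproducibility", {
  assoc <- list(m1 = "drought", m2 = "drought", m3 = c("drought", "cold"),
                m4 = "cold", m5 = "virus")
  all_m <- c(names(assoc), "m6", "m7")
  ex <- stress_pair_experiment(assoc, all_m, n_negative_sets = 10,
                               seed = 3)
  # sharing pairs: m1m2, m1m3, m2m3 (drought), m3m4 (cold) -> 4
  expect_setequal(ex$positives,
                  c(pair_key("m1", "m2"), pair_key("m1", "m3"),
                    pair_key("m2", "m3"), pair_key("m3", "m4")))
  expect_length(ex$negative_sets, 10)
  for (ns in ex$negative_sets) {
    expect_length(ns, length(ex$positives))
    for (p in ns) {   # brute-force label check
      ab <- strsplit(p, "|", fixed = TRUE)[[1]]
      la <- assoc[[ab[1]]]; lb <- assoc[[ab[2]]]
      expect_length(intersect(if (is.null(la)) character(0) else la,
                              if (is.null(lb)) character(0) else lb), 0)
    }
  }
  ex2 <- stress_pair_experiment(assoc, all_m, n_negative_sets = 10,
                                seed = 3)
  expect_identical(ex2$negative_sets, ex$negative_sets)
})
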