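#' Specification for a synthetic fixture bundle
#'
#' Describes a fully synthetic, self-contained data bundle — toy GO
#' DAGs, gene annotations, PPI edge lists, miRNA target sets, family /
#' genomic-cluster / stress labels — with controllable effect sizes, so
#' that every pipeline stage can be exercised and calibrated without any
#' external download.  Generation is a pure function of this
#' specification object: the same settings (including the seed) always
#' yield byte-identical files.
#'
#' The designed signal works in two ways: miRNAs in the same family (or
#' stress group) share a `family_effect` (`stress_effect`) fraction of
#' their target genes, and each shared-target pool is planted as a
#' clique of the network whose members carry near-identical annotations,
#' so the shared targets sit in one densely connected, semantically
#' homogeneous neighborhood.
#'
#' @param n_terms terms per ontology aspect (including the root).
#' @param max_depth maximum DAG depth below the root.
#' @param part_of_fraction fraction of child-parent edges tagged
#'   `part_of` rather than `is_a`.
#' @param aspects which GO aspects to generate.
#' @param n_genes number of network genes.
#' @param edge_prob Erdos-Renyi edge probability of the network core.
#' @param terms_per_gene range (min, max) of annotated terms per gene
#'   and aspect.
#' @param unannotated_fraction fraction of genes left without any
#'   annotation (their edges become non-traversable).
#' @param n_mirnas number of miRNAs.
#' @param targets_per_mirna range (min, max) of target genes per miRNA;
#'   plant miRNAs have only a handful of targets, so the default is
#'   small.
#' @param orphan_target_fraction fraction of each miRNA's non-shared
#'   targets drawn from genes absent from the network (exercising the
#'   exclusion counts of the set-level score).
#' @param n_families,family_size miRNA families (each of `family_size`
#'   members).
#' @param family_effect fraction of targets shared within a family, in
#'   \[0, 1\].
#' @param n_stress_groups,stress_group_size,stress_effect analogous
#'   planted stress-response groups.
#' @param n_clusters number of genomic clusters: in the first
#'   `n_clusters` families, the first two members are placed within
#'   2 kb of each other (all other inter-gene gaps are 50 kb).
#' @param seed integer seed.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 40, max_depth = 4,
                         part_of_fraction = 0.2,
                         aspects = c("BP", "CC", "MF"),
                         n_genes = 150, edge_prob = 0.04,
                         terms_per_gene = c(2, 4),
                         unannotated_fraction = 0.1,
                         n_mirnas = 70, targets_per_mirna = c(4, 8),
                         orphan_target_fraction = 0.1,
                         n_families = 17, family_size = 3,
                         family_effect = 0.5,
                         n_stress_groups = 3, stress_group_size = 4,
                         stress_effect = 0.75,
                         n_clusters = 5, seed = 1L) {
  spec <- list(n_terms = n_terms, max_depth = max_depth,
               part_of_fraction = part_of_fraction,
               aspects = match.arg(aspects, several.ok = TRUE),
               n_genes = n_genes, edge_prob = edge_prob,
               terms_per_gene = terms_per_gene,
               unannotated_fraction = unannotated_fraction,
               n_mirnas = n_mirnas, targets_per_mirna = targets_per_mirna,
               orphan_target_fraction = orphan_target_fraction,
               n_families = n_families, family_size = family_size,
               family_effect = family_effect,
               n_stress_groups = n_stress_groups,
               stress_group_size = stress_group_size,
               stress_effect = stress_effect,
               n_clusters = n_clusters, seed = as.integer(seed))
  with(spec, {
    if (n_terms < 2 || max_depth < 1 || n_genes < 2 || n_mirnas < 2) {
      stop("fixture spec counts must be positive (and sets non-trivial)")
    }
    if (any(c(part_of_fraction, unannotated_fraction,
              orphan_target_fraction, family_effect, stress_effect) < 0) ||
        any(c(part_of_fraction, unannotated_fraction,
              orphan_target_fraction, family_effect, stress_effect) > 1)) {
      stop("fixture spec fractions must lie in [0, 1]")
    }
    if (targets_per_mirna[1] > targets_per_mirna[2] ||
        targets_per_mirna[1] < 1) {
      stop("invalid targets_per_mirna range")
    }
    if (n_families * family_size + n_stress_groups * stress_group_size >
        n_mirnas) {
      stop("n_mirnas too small for the requested families and stress groups")
    }
    if (n_clusters > n_families) stop("n_clusters cannot exceed n_families")
  })
  structure(spec, class = "fixture_spec")
}

stress_vocabulary <- function() {
  c("drought", "salt", "cold", "heat", "oxidative", "uv", "wounding",
    "flooding", "nutrient", "osmotic", "aba", "hypoxia",   # abiotic
    "bacteria", "fungus", "virus")                         # biotic
}

# one layered random DAG with a single root; term ids carry an
# aspect-specific block so aspects never collide
generate_aspect_ontology <- function(spec, aspect) {
  offset <- c(BP = 1e6, CC = 2e6, MF = 3e6)[[aspect]]
  ids <- sprintf("GO:%07d", offset + seq_len(spec$n_terms))
  depth <- c(0L, 1L + ((seq_len(spec$n_terms - 1L) - 1L) %% spec$max_depth))
  depth <- sort(depth)  # root first, then filled layer by layer
  parents <- stats::setNames(vector("list", spec$n_terms), ids)
  relations <- parents
  for (i in seq_along(ids)) {
    parents[[i]] <- character(0); relations[[i]] <- character(0)
    if (depth[i] == 0L) next
    shallower <- ids[depth < depth[i]]
    k <- min(length(shallower), sample(1:2, 1))
    p <- sample(shallower, k)
    parents[[i]] <- p
    relations[[i]] <- ifelse(stats::runif(k) < spec$part_of_fraction,
                             "part_of", "is_a")
  }
  ontology_graph(ids, parents, relations, aspect)
}

#' Generate a synthetic fixture bundle
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory: when given, the bundle is also
#'   written in the package's external-interface dialects (OBO, GAF,
#'   2-column edge-list TSVs, target / family / coordinate / stress
#'   TSVs) and the file paths are returned under `$paths`.
#' @return list with in-memory components: `spec`, `ontology` (named
#'   list of [ontology_graph]s), `annotations` (named list of
#'   [annotation_map]s), `network` ([ppi_network][integrate_edge_lists]),
#'   `target_sets`, `families`, `stress`, `coords`, `clique_genes`, and
#'   optionally `paths`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, generate_fixture_impl(spec, dir))
}

generate_fixture_impl <- function(spec, dir) {
  ontology <- stats::setNames(
    lapply(spec$aspects, function(a) generate_aspect_ontology(spec, a)),
    spec$aspects)

  genes <- sprintf("G%04d", seq_len(spec$n_genes))

  ## ---- miRNA groups -------------------------------------------------
  mirnas <- sprintf("mir%03d", seq_len(spec$n_mirnas))
  fam_members <- split(mirnas[seq_len(spec$n_families * spec$family_size)],
                       rep(seq_len(spec$n_families), each = spec$family_size))
  names(fam_members) <- sprintf("FAM%02d", seq_len(spec$n_families))
  stress_start <- spec$n_families * spec$family_size
  stress_members <- split(
    mirnas[stress_start + seq_len(spec$n_stress_groups * spec$stress_group_size)],
    rep(seq_len(spec$n_stress_groups), each = spec$stress_group_size))
  vocab <- stress_vocabulary()
  names(stress_members) <- vocab[seq_len(spec$n_stress_groups)]

  families <- stats::setNames(rep(names(fam_members), lengths(fam_members)),
                              unlist(fam_members))
  stress <- lapply(stats::setNames(nm = unlist(stress_members)), function(m) {
    names(stress_members)[vapply(stress_members, function(g) m %in% g,
                                 logical(1))]
  })

  ## ---- target sets with planted sharing ----------------------------
  available <- genes
  take_clique <- function(k) {
    if (k > length(available)) stop("fixture infeasible: not enough genes ",
                                    "for the requested shared-target cliques")
    g <- available[seq_len(k)]
    available <<- available[-seq_len(k)]
    g
  }
  rng_targets <- function() {
    sample(spec$targets_per_mirna[1]:spec$targets_per_mirna[2], 1)
  }
  orphan_counter <- 0L
  draw_private <- function(k, exclude) {
    n_orphan <- stats::rbinom(1, k, spec$orphan_target_fraction)
    pool <- setdiff(genes, exclude)
    if (k - n_orphan > length(pool)) stop("fixture infeasible: target sets ",
                                          "larger than the gene universe")
    inn <- sample(pool, k - n_orphan)
    orph <- if (n_orphan > 0) {
      o <- sprintf("X%04d", orphan_counter + seq_len(n_orphan))
      orphan_counter <<- orphan_counter + n_orphan
      o
    } else character(0)
    c(inn, orph)
  }

  target_sets <- stats::setNames(vector("list", spec$n_mirnas), mirnas)
  clique_genes <- list()
  plant_group <- function(members, effect, label) {
    t_n <- rng_targets()
    n_shared <- round(effect * t_n)
    shared <- if (n_shared > 0) take_clique(n_shared) else character(0)
    if (length(shared)) clique_genes[[label]] <<- shared
    for (m in members) {
      target_sets[[m]] <<- c(shared, draw_private(t_n - n_shared, shared))
    }
  }
  for (f in names(fam_members)) {
    plant_group(fam_members[[f]], spec$family_effect, f)
  }
  for (s in names(stress_members)) {
    plant_group(stress_members[[s]], spec$stress_effect, paste0("STR_", s))
  }
  ungrouped <- mirnas[vapply(target_sets, is.null, logical(1))]
  for (m in ungrouped) {
    target_sets[[m]] <- draw_private(rng_targets(), character(0))
  }

  ## ---- network: ER core + planted cliques --------------------------
  er <- which(upper.tri(matrix(0, spec$n_genes, spec$n_genes)) &
                matrix(stats::runif(spec$n_genes^2) < spec$edge_prob,
                       spec$n_genes, spec$n_genes),
              arr.ind = TRUE)
  er_edges <- data.frame(a = genes[er[, 1]], b = genes[er[, 2]],
                         stringsAsFactors = FALSE)
  clique_edges <- do.call(rbind, lapply(clique_genes, function(g) {
    if (length(g) < 2L) return(NULL)
    cmb <- utils::combn(g, 2L)
    data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
  }))
  # anchor each clique to the ER core so shared targets stay reachable
  anchors <- do.call(rbind, lapply(clique_genes, function(g) {
    data.frame(a = g[1], b = sample(setdiff(genes, g), 1),
               stringsAsFactors = FALSE)
  }))
  # two overlapping "databases", exercising union/dedup on integration
  half <- seq_len(floor(nrow(er_edges) / 2))
  sources <- list(
    dbA = rbind(er_edges, anchors),
    dbB = rbind(er_edges[half, , drop = FALSE], clique_edges, anchors))
  network <- integrate_edge_lists(sources)

  ## ---- annotations: homogeneous inside cliques ---------------------
  n_unann <- round(spec$unannotated_fraction * spec$n_genes)
  unannotated <- sample(setdiff(genes, unlist(clique_genes)),
                        min(n_unann, length(setdiff(genes, unlist(clique_genes)))))
  annotations <- list(); gaf_rows <- list()
  for (asp in spec$aspects) {
    terms <- ontology[[asp]]$terms[-1]  # non-root terms
    g2t <- stats::setNames(vector("list", spec$n_genes), genes)
    for (cg in clique_genes) {
      base <- sample(terms, sample(spec$terms_per_gene[1]:spec$terms_per_gene[2], 1))
      for (g in cg) g2t[[g]] <- base
    }
    for (g in setdiff(genes, c(unlist(clique_genes), unannotated))) {
      g2t[[g]] <- sample(terms,
                         sample(spec$terms_per_gene[1]:spec$terms_per_gene[2], 1))
    }
    for (g in unannotated) g2t[[g]] <- character(0)
    annotations[[asp]] <- annotation_map(g2t, ontology[[asp]])
    code <- c(BP = "P", CC = "C", MF = "F")[[asp]]
    ann_g <- names(g2t)[lengths(g2t) > 0]
    gaf_rows[[asp]] <- data.frame(
      gene = rep(ann_g, lengths(g2t[ann_g])),
      go = unlist(g2t[ann_g], use.names = FALSE),
      aspect = code, stringsAsFactors = FALSE)
  }

  ## ---- genome coordinates ------------------------------------------
  coords <- data.frame(mirna = mirnas, chrom = "", start = 0L, end = 0L,
                       strand = "+", stringsAsFactors = FALSE)
  pos <- 1000L; chrom <- "Chr1"
  clustered_fams <- names(fam_members)[seq_len(spec$n_clusters)]
  for (i in seq_along(mirnas)) {
    m <- mirnas[i]
    gap <- 50000L
    if (i > 1L) {
      prev <- mirnas[i - 1L]
      same_fam <- !is.na(families[m]) && !is.na(families[prev]) &&
        identical(unname(families[m]), unname(families[prev]))
      if (same_fam && families[[m]] %in% clustered_fams &&
          match(m, fam_members[[families[[m]]]]) == 2L) {
        gap <- 2000L   # second family member lands inside the 10-kb rule
      }
    }
    pos <- pos + gap
    coords$chrom[i] <- chrom
    coords$start[i] <- pos
    coords$end[i] <- pos + 120L
    pos <- coords$end[i]
  }

  bundle <- list(spec = spec, ontology = ontology,
                 annotations = annotations, network = network,
                 target_sets = target_sets, families = families,
                 stress = stress, coords = coords,
                 clique_genes = clique_genes)
  if (!is.null(dir)) bundle$paths <- write_fixture_files(bundle, sources,
                                                         gaf_rows, dir)
  bundle
}

write_obo_file <- function(ontology, path) {
  ns <- c(BP = "biological_process", CC = "cellular_component",
          MF = "molecular_function")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", "ontology: fixture"), con)
  for (asp in names(ontology)) {
    g <- ontology[[asp]]
    for (t in g$terms) {
      writeLines(c("", "[Term]", paste0("id: ", t),
                   paste0("name: ", t), paste0("namespace: ", ns[[asp]])),
                 con)
      p <- g$parents[[t]]; r <- g$relations[[t]]
      for (k in seq_along(p)) {
        if (r[k] == "is_a") writeLines(paste0("is_a: ", p[k]), con)
        else writeLines(paste0("relationship: part_of ", p[k]), con)
      }
    }
  }
  path
}

write_fixture_files <- function(bundle, sources, gaf_rows, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list()
  p$obo <- write_obo_file(bundle$ontology, file.path(dir, "ontology.obo"))

  gaf <- do.call(rbind, gaf_rows)
  gaf_tab <- data.frame(db = "FIX", id = gaf$gene, symbol = gaf$gene,
                        qualifier = "", go = gaf$go, ref = "FIX:0000001",
                        evidence = "IDA", with = "", aspect = gaf$aspect,
                        name = "", synonym = "", type = "protein",
                        taxon = "taxon:3702", date = "20150101",
                        assigned_by = "FIX", ext = "", product = "")
  p$gaf <- file.path(dir, "annotations.gaf")
  writeLines("!gaf-version: 2.1", p$gaf)
  suppressWarnings(utils::write.table(gaf_tab, p$gaf, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      col.names = FALSE, append = TRUE))
  p$edges <- character(0)
  for (s in names(sources)) {
    f <- file.path(dir, paste0("edges_", s, ".tsv"))
    utils::write.table(sources[[s]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    p$edges <- c(p$edges, f)
  }
  tg <- data.frame(
    mirna = rep(names(bundle$target_sets), lengths(bundle$target_sets)),
    gene = unlist(bundle$target_sets, use.names = FALSE))
  p$targets <- file.path(dir, "targets.tsv")
  utils::write.table(tg, p$targets, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  p$families <- file.path(dir, "families.tsv")
  utils::write.table(
    data.frame(mirna = names(bundle$families),
               family = unname(bundle$families)),
    p$families, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  p$coords <- file.path(dir, "coords.tsv")
  utils::write.table(bundle$coords, p$coords, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  st <- data.frame(
    mirna = rep(names(bundle$stress), lengths(bundle$stress)),
    label = unlist(bundle$stress, use.names = FALSE))
  p$stress <- file.path(dir, "stress.tsv")
  utils::write.table(st, p$stress, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  p
}
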