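#' The six target-prediction algorithms recognized by the schema
#' @return Character vector of algorithm names.
#' @export
prediction_algorithms <- function() {
  c("DIANA-microTv4.0", "miRanda-rel2010", "PicTar2", "PITA", "RNA22v2",
    "Targetscan6.2")
}

validate_predictions <- function(preds) {
  need <- c("mirna", "gene", "algorithm")
  if (!all(need %in% names(preds)))
    stop_invalid("prediction table needs columns: %s",
                 paste(need, collapse = ", "))
  bad <- setdiff(unique(preds$algorithm), prediction_algorithms())
  if (length(bad))
    stop_invalid("unknown prediction algorithm(s): %s",
                 paste(bad, collapse = ", "))
  unique(preds[, need])
}

#' Bona-fide miRNA target calling by algorithm consensus
#'
#' A (miRNA, gene) interaction is bona fide when supported by at least
#' `min_algorithms` distinct prediction algorithms out of the declared
#' six-member set. Duplicate (miRNA, gene, algorithm) rows count once.
#'
#' @param preds data.frame with columns `mirna`, `gene`, `algorithm`.
#' @param min_algorithms consensus threshold (default 2).
#' @return Named list: per miRNA, the character vector of bona-fide target
#'   genes. Anti-monotone in `min_algorithms`.
#' @export
bona_fide_targets <- function(preds, min_algorithms = 2L) {
  preds <- validate_predictions(preds)
  min_algorithms <- check_count(min_algorithms, "min_algorithms")
  key <- paste(preds$mirna, preds$gene, sep = "\r")
  support <- table(key)
  keep <- names(support)[support >= min_algorithms]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  mirna <- vapply(parts, `[`, "", 1L)
  gene <- vapply(parts, `[`, "", 2L)
  lapply(split(gene, mirna), function(g) sort(unique(g)))
}

validate_diseases <- function(diseases, min_genes = 20L) {
  need <- c("disease", "gene", "curated")
  if (!all(need %in% names(diseases)))
    stop_invalid("disease table needs columns: %s",
                 paste(need, collapse = ", "))
  cur <- diseases[as.logical(diseases$curated), c("disease", "gene")]
  cur <- unique(cur)
  sets <- lapply(split(cur$gene, cur$disease), function(g) sort(unique(g)))
  sets[vapply(sets, length, 0L) >= min_genes]
}

#' Disease-gene sets from a curated association table
#'
#' Keeps only expert-curated rows and diseases with at least `min_genes`
#' associated genes.
#'
#' @param diseases data.frame with columns `disease`, `gene`, `curated`.
#' @param min_genes minimum curated gene-set size (default 20).
#' @return Named list of gene sets.
#' @export
disease_gene_sets <- function(diseases, min_genes = 20L) {
  validate_diseases(diseases, min_genes)
}

#' Per-disease Fisher enrichment of miRNA targets
#'
#' For every (miRNA, disease) pair — plus a pooled set that unions all
#' disease genes — a one-sided (over-representation) Fisher exact test on
#' the 2x2 table of target membership versus disease membership over the
#' gene universe, with BH FDR across all tests in the run. The default
#' universe is the union of all genes in the prediction table; results are
#' sensitive to this choice, so the universe is an explicit argument.
#'
#' @param targets miRNA -> gene-set map from [bona_fide_targets()].
#' @param disease_sets named list of disease gene sets from
#'   [disease_gene_sets()].
#' @param universe character vector of background genes.
#' @param fdr_threshold FDR threshold for the enriched flag (default 0.1).
#' @param pooled_label name of the pooled all-disease set (`NULL` to skip).
#' @return data.frame of class `enrichment_result`: mirna, disease,
#'   n11 (targets in disease), n12 (targets outside), n21 (disease
#'   non-targets), n22 (neither), odds_ratio (sample cross-product ratio),
#'   p_fisher, p_fdr, enriched. The four counts always sum to the universe
#'   size.
#' @export
disease_enrichment <- function(targets, disease_sets, universe = NULL,
                               fdr_threshold = 0.1,
                               pooled_label = "all diseases (pooled)") {
  if (is.null(universe))
    universe <- sort(unique(unlist(targets, use.names = FALSE)))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_invalid("empty gene universe")
  if (!is.null(pooled_label))
    disease_sets[[pooled_label]] <-
      sort(unique(unlist(disease_sets, use.names = FALSE)))
  rows <- list()
  for (mi in names(targets)) {
    tg <- intersect(targets[[mi]], universe)
    for (ds in names(disease_sets)) {
      dg <- intersect(disease_sets[[ds]], universe)
      n11 <- length(intersect(tg, dg))
      n12 <- length(tg) - n11
      n21 <- length(dg) - n11
      n22 <- length(universe) - n11 - n12 - n21
      p <- stats::fisher.test(matrix(c(n11, n21, n12, n22), 2L),
                              alternative = "greater")$p.value
      or <- (n11 * n22) / (n12 * n21)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mi, disease = ds, n11 = n11, n12 = n12, n21 = n21,
        n22 = n22, odds_ratio = or, p_fisher = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_fisher)
  out$enriched <- out$p_fdr < fdr_threshold
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Hub genes across diseases
#'
#' Genes belonging to at least `min_diseases` disease sets, annotated with
#' the number of diseases and the number of bona-fide miRNAs targeting
#' them, sorted by (targeting miRNAs descending, gene id).
#'
#' @param targets miRNA -> gene-set map.
#' @param disease_sets named list of disease gene sets.
#' @param min_diseases membership threshold (default 4).
#' @return data.frame: gene, n_diseases, n_targeting_mirnas.
#' @export
hub_genes <- function(targets, disease_sets, min_diseases = 4L) {
  if (!length(disease_sets))
    return(data.frame(gene = character(), n_diseases = integer(),
                      n_targeting_mirnas = integer(),
                      stringsAsFactors = FALSE))
  memb <- table(unlist(lapply(disease_sets, unique), use.names = FALSE))
  hubs <- names(memb)[memb >= min_diseases]
  n_t <- vapply(hubs, function(g)
    sum(vapply(targets, function(tg) g %in% tg, TRUE)), 0L)
  out <- data.frame(gene = hubs, n_diseases = as.integer(memb[hubs]),
                    n_targeting_mirnas = as.integer(n_t),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_targeting_mirnas, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway coverage overlay
#'
#' For each gene of a pathway (e.g. the coagulation cascade), lists the
#' supplied miRNAs targeting it and summarizes coverage as the count of
#' covered genes over the pathway size. Coverage is monotone nondecreasing
#' in the miRNA set.
#'
#' @param targets miRNA -> gene-set map.
#' @param pathway_genes non-empty character vector of pathway genes.
#' @return list with `per_gene` (data.frame: gene, mirnas, n_mirnas),
#'   `n_covered`, `n_pathway`.
#' @export
pathway_overlay <- function(targets, pathway_genes) {
  pathway_genes <- unique(as.character(pathway_genes))
  if (!length(pathway_genes)) stop_invalid("pathway gene list is empty")
  per <- lapply(pathway_genes, function(g) {
    hits <- names(targets)[vapply(targets, function(tg) g %in% tg, TRUE)]
    data.frame(gene = g, mirnas = paste(sort(hits), collapse = ";"),
               n_mirnas = length(hits), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_gene = per, n_covered = sum(per$n_mirnas > 0L),
       n_pathway = nrow(per))
}

#' Build a synthetic miRNA-target / disease-gene fixture
#'
#' Constructs small edge tables with the structural features the network
#' stage expects: nine miRNAs, a gene universe, six-algorithm predictions
#' with a consensus structure, curated disease sets of >= 20 genes, a hub
#' gene present in five diseases and targeted by six of the nine miRNAs,
#' and a 36-gene pathway of which 27 are covered by the five mediator
#' miRNAs. Entirely synthetic; it mirrors database exports structurally,
#' not any real database content.
#'
#' @param seed RNG seed.
#' @param n_genes universe size.
#' @return list: `predictions`, `diseases` (data.frames), `pathway_genes`,
#'   `mirnas`, `mediator_mirnas`, `hub_gene`.
#' @export
build_network_fixture <- function(seed = 1L, n_genes = 400L) {
  with_seed(string_seed(seed, "network"), {
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    mirnas <- sprintf("miR-%02d", 1:9)
    mediators <- mirnas[1:5]
    hub <- "GENE001"
    algs <- prediction_algorithms()
    rows <- list()
    for (mi in mirnas) {
      tg <- sample(genes, 60)
      for (g in tg) {
        k <- sample(0:4, 1L, prob = c(0.25, 0.3, 0.25, 0.15, 0.05)) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mi, gene = g, algorithm = sample(algs, k),
          stringsAsFactors = FALSE)
      }
    }
    preds <- do.call(rbind, rows)
    # the hub gene: bona-fide target of six of the nine miRNAs
    hub_rows <- do.call(rbind, lapply(mirnas[1:6], function(mi)
      data.frame(mirna = mi, gene = hub, algorithm = algs[1:3],
                 stringsAsFactors = FALSE)))
    preds <- unique(rbind(preds[preds$gene != hub, ], hub_rows))

    diseases <- c("Myocardial Ischemia", "Hypertensive Diseases",
                  "Inflammation", "Heart Failure", "Thrombosis",
                  "Atrial Fibrillation")
    bona <- bona_fide_targets(preds)
    drows <- lapply(seq_along(diseases), function(k) {
      # the first three diseases draw over half their genes from one
      # miRNA's bona-fide target set, planting true enrichment
      g <- if (k <= 3) {
        pool <- bona[[mirnas[k]]]
        unique(c(sample(pool, min(18, length(pool))), sample(genes, 14)))
      } else sample(genes, 30)
      data.frame(disease = diseases[k], gene = g, curated = TRUE,
                 stringsAsFactors = FALSE)
    })
    dtab <- do.call(rbind, drows)
    dtab <- rbind(dtab,
                  data.frame(disease = diseases[1:5], gene = hub,
                             curated = TRUE, stringsAsFactors = FALSE),
                  data.frame(disease = diseases[1],
                             gene = sample(genes, 10), curated = FALSE,
                             stringsAsFactors = FALSE))
    dtab <- unique(dtab)

    # 36-gene pathway, exactly 27 covered by the mediator miRNAs
    med_targets <- bona_fide_targets(preds)[mediators]
    covered_pool <- sort(unique(unlist(med_targets)))
    uncovered_pool <- setdiff(genes, covered_pool)
    pathway <- c(sample(covered_pool, 27), sample(uncovered_pool, 9))
    list(predictions = preds, diseases = dtab,
         pathway_genes = sample(pathway), mirnas = mirnas,
         mediator_mirnas = mediators, hub_gene = hub)
  })
}
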