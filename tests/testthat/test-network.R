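algs <- prediction_algorithms()

pred_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(mirna = r[[1]], gene = r[[2]], algorithm = r[[3]],
               stringsAsFactors = FALSE)))
}

test_that("bona_fide_targets enforces the >=2-algorithm consensus", {
  preds <- pred_df(
    list("m1", "G1", algs[1]),                 # 1 algorithm: dropped
    list("m1", "G2", algs[1]), list("m1", "G2", algs[2]), # 2: kept
    list("m1", "G3", algs[1]), list("m1", "G3", algs[1]), # duplicate row: 1
    list("m2", "G1", algs[3]), list("m2", "G1", algs[4])
  )
  tg <- bona_fide_targets(preds)
  expect_identical(tg$m1, "G2")
  expect_identical(tg$m2, "G1")

  # threshold 1 is the raw edge set; threshold anti-monotonicity
  tg1 <- bona_fide_targets(preds, 1)
  expect_setequal(tg1$m1, c("G1", "G2", "G3"))
  for (mi in names(tg)) expect_true(all(tg[[mi]] %in% tg1[[mi]]))

  bad <- pred_df(list("m1", "G1", "MadeUpAlgorithm"))
  expect_error(bona_fide_targets(bad), "unknown prediction algorithm")
})

test_that("disease_gene_sets keeps curated diseases with >= 20 genes", {
  d <- rbind(
    data.frame(disease = "big", gene = sprintf("G%02d", 1:25), curated = TRUE),
    data.frame(disease = "small", gene = sprintf("G%02d", 1:5), curated = TRUE),
    data.frame(disease = "uncurated", gene = sprintf("G%02d", 1:30),
               curated = FALSE)
  )
  sets <- disease_gene_sets(d)
  expect_identical(names(sets), "big")
  expect_length(sets$big, 25L)
})

test_that("Fisher enrichment p equals direct hypergeometric tail summation", {
  # constructed 2x2 of (8, 2, 10, 80) over a 100-gene universe
  universe <- sprintf("G%03d", 1:100)
  targets <- list(m1 = universe[1:10])
  dis <- list(D = universe[c(1:8, 11:20)])
  res <- disease_enrichment(targets, dis, universe, pooled_label = NULL)
  expect_equal(res$n11, 8); expect_equal(res$n12, 2)
  expect_equal(res$n21, 10); expect_equal(res$n22, 80)
  expect_equal(res$n11 + res$n12 + res$n21 + res$n22, 100)

  tail_p <- sum(vapply(8:10, function(k)
    choose(18, k) * choose(82, 10 - k), 0)) / choose(100, 10)
  expect_equal(res$p_fisher, tail_p, tolerance = 1e-12)

  # random small tables vs the same brute-force oracle
  set.seed(12)
  for (rep in 1:20) {
    N <- sample(30:150, 1)
    uni <- sprintf("g%03d", 1:N)
    K <- sample(5:15, 1); D <- sample(5:20, 1)
    tg <- list(mx = sample(uni, K))
    ds <- list(dx = sample(uni, D))
    r <- disease_enrichment(tg, ds, uni, pooled_label = NULL)
    k11 <- r$n11
    oracle <- sum(vapply(k11:min(K, D), function(k)
      choose(D, k) * choose(N - D, K - k), 0)) / choose(N, K)
    expect_equal(r$p_fisher, oracle, tolerance = 1e-10)
  }
})

test_that("enrichment edge cases: disease set = universe, doubling counts, row order", {
  universe <- sprintf("G%03d", 1:60)
  targets <- list(m1 = universe[1:12])
  res <- disease_enrichment(targets, list(all = universe), universe,
                            pooled_label = NULL)
  expect_equal(res$p_fisher, 1)

  # doubling every count preserves the odds ratio and shrinks p
  p_small <- fisher.test(matrix(c(8, 10, 2, 80), 2), alternative = "greater")$p.value
  p_big <- fisher.test(matrix(c(16, 20, 4, 160), 2), alternative = "greater")$p.value
  expect_lt(p_big, p_small)

  fx <- build_network_fixture(seed = 5)
  tg <- bona_fide_targets(fx$predictions)
  ds <- disease_gene_sets(fx$diseases)
  r1 <- disease_enrichment(tg, ds)
  # the fixture plants true enrichment: the first disease's genes are drawn
  # largely from miR-01's bona-fide targets
  expect_true(r1$enriched[r1$mirna == "miR-01" &
                            r1$disease == "Myocardial Ischemia"])
  shuf <- fx$predictions[sample(nrow(fx$predictions)), ]
  r2 <- disease_enrichment(bona_fide_targets(shuf), ds)
  expect_equal(r1[order(r1$mirna, r1$disease), ],
               r2[order(r2$mirna, r2$disease), ], ignore_attr = TRUE)
  expect_true(all(r1$enriched == (r1$p_fdr < 0.1)))
  expect_error(disease_enrichment(tg, ds, character()), "empty gene universe")
})

test_that("hub genes require the disease-membership threshold and sort by targeting miRNAs", {
  fx <- build_network_fixture(seed = 2)
  tg <- bona_fide_targets(fx$predictions)
  ds <- disease_gene_sets(fx$diseases)
  hubs <- hub_genes(tg, ds, min_diseases = 4)
  expect_true(fx$hub_gene %in% hubs$gene)
  top <- hubs[hubs$gene == fx$hub_gene, ]
  expect_gte(top$n_diseases, 4L)
  expect_gte(top$n_targeting_mirnas, 6L)
  expect_identical(hubs$gene[1], fx$hub_gene)
  expect_true(all(diff(hubs$n_targeting_mirnas) <= 0))

  # a gene in only 3 diseases is excluded at the default threshold
  ds3 <- list(a = "G1", b = "G1", c = "G1", d = "G2", e = "G2", f = "G2",
              g = "G2")
  h <- hub_genes(list(m = c("G1", "G2")), ds3, min_diseases = 4)
  expect_identical(h$gene, "G2")
  expect_identical(nrow(hub_genes(list(m = "G1"), list(), 4)), 0L)
})

test_that("pathway overlay reports per-gene coverage and is monotone in the miRNA set", {
  fx <- build_network_fixture(seed = 3)
  tg <- bona_fide_targets(fx$predictions)
  med <- tg[fx$mediator_mirnas]
  ov <- pathway_overlay(med, fx$pathway_genes)
  expect_equal(ov$n_pathway, 36L)
  expect_equal(ov$n_covered, 27L)

  none <- pathway_overlay(list(m = "NOT_A_GENE"), fx$pathway_genes)
  expect_equal(none$n_covered, 0L)

  ov_all <- pathway_overlay(tg, fx$pathway_genes)
  expect_gte(ov_all$n_covered, ov$n_covered)
  expect_error(pathway_overlay(tg, character()), "empty")
})
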