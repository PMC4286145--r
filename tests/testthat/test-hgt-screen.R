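code <- genetic_code()

test_that("fold change is symmetric, total, and handles zero/undefined", {
  expect_equal(fold_change(1.5, 0.5), 3)
  expect_equal(fold_change(0.5, 1.5), 3)
  expect_equal(fold_change(1.2, 1.2), 1)
  expect_identical(fold_change(0.8, 0), Inf)
  expect_true(is.na(fold_change(0, 1)))     # codon unused by the gene
  expect_true(is.na(fold_change(NA, 1)))
  expect_true(is.na(fold_change(1, NA)))    # background undefined
  set.seed(1)
  g <- runif(59, 0.01, 4); b <- runif(59, 0.01, 4)
  expect_equal(fold_change(g, b), fold_change(b, g))
  expect_true(all(fold_change(g, b) >= 1))
})

test_that("screen_gene counts used and changed codons per the fold/fraction rule", {
  # gene uses 4 degenerate codons; background tuned so the symmetric fold
  # changes are {1.5, 2, 2, 1.6}
  gene <- paste0(strrep("TTT", 3), "TTC",              # Phe RSCU 1.5 / 0.5
                 strrep("GGA", 2), strrep("GGC", 2))   # Gly RSCU 2, 2, 0, 0
  ct <- count_codons(gene, code)
  bg_gene <- paste0(strrep("TTT", 1), strrep("TTC", 1),  # Phe 1:1 -> 1, 1
                    strrep("GGA", 4), strrep("GGC", 5),
                    strrep("GGG", 5), strrep("GGT", 2))  # Gly RSCUs 1,1.25,1.25,0.5
  bg <- composition_profile(count_codons(bg_gene, code), code)
  res <- screen_gene(ct, bg, code, screen_params(), gene_id = "t1")
  # folds: TTT 1.5/1=1.5, TTC 0.5/1=2, GGA 2/1=2, GGC 2/1.25=1.6 -> none > 2 strictly
  expect_equal(res$n_used, 4)
  expect_equal(res$n_changed, 0)
  # with fold threshold 1.45 all but none... folds {1.5, 2, 2, 1.6} all > 1.45
  res2 <- screen_gene(ct, bg, code, screen_params(fold_threshold = 1.45),
                      gene_id = "t1")
  expect_equal(res2$n_changed, 4)
  expect_equal(res2$fraction_changed, 1)
  expect_true(res2$rscu_flag)
})

test_that("a gene identical to the background is never flagged", {
  set.seed(21)
  s <- random_cds(300)
  bg <- composition_profile(count_codons(s, code), code)
  res <- screen_gene(count_codons(s, code), bg, code)
  expect_equal(res$n_changed, 0)
  expect_false(res$rscu_flag)
  expect_equal(res$gc_delta, 0)
  expect_false(res$gc_flag)
})

test_that("screening requires degenerate codons", {
  met_only <- count_codons("ATGATGATG", code)
  bg <- composition_profile(count_codons(random_cds(100), code), code)
  expect_error(screen_gene(met_only, bg, code), "degenerate")
})

test_that("raising either threshold never increases flags (monotonicity)", {
  sim <- simulate_genome(n_background = 30, n_alien = 6,
                         len_codons_range = c(60, 150),
                         bg_profile = make_profile(0.8),
                         alien_profile = make_profile(0.35), seed = 5)
  folds <- c(1.5, 2, 3, 5)
  n_changed_tot <- sapply(folds, function(f) {
    sum(screen_genome(sim$genes,
                      params = screen_params(fold_threshold = f))$n_changed)
  })
  expect_true(all(diff(n_changed_tot) <= 0))
  fracs <- c(0.1, 0.25, 0.5, 0.9)
  n_flagged <- sapply(fracs, function(q) {
    sum(screen_genome(sim$genes,
                      params = screen_params(fraction_threshold = q))$rscu_flag)
  })
  expect_true(all(diff(n_flagged) <= 0))
})

test_that("gene order does not change screen results", {
  sim <- simulate_genome(n_background = 12, n_alien = 3,
                         len_codons_range = c(50, 90), seed = 8)
  genes <- setNames(sim$genes$sequence, sim$genes$gene_id)
  r1 <- screen_genome(genes)
  set.seed(2); perm <- sample(length(genes))
  r2 <- screen_genome(genes[perm])
  r2 <- r2[match(r1$gene_id, r2$gene_id), ]
  rownames(r2) <- NULL
  attr(r1, "summary") <- attr(r2, "summary") <- NULL
  expect_equal(r1, r2)
})

test_that("the pooled background screened against itself shows no change", {
  set.seed(31)
  genes <- random_gene_set(10, c(40, 100))
  pooled <- pool_background(genes, code)
  res <- screen_gene(pooled$counts, pooled$profile, code, gene_id = "pool")
  expect_equal(res$n_changed, 0)
  expect_false(res$rscu_flag)
})

test_that("classify_hit resolves families by genus and flags unknowns as NA", {
  cls <- classify_hit(c("Burkholderia cepacia", "Halomonas lutea",
                        "Chromohalobacter salexigens", "Halomonas sp.",
                        "Mysterivibrio abyssi"))
  expect_equal(cls$foreign_hit, c(TRUE, FALSE, FALSE, FALSE, NA))
  expect_equal(cls$family[1], "Burkholderiaceae")
  expect_equal(cls$family[5], "unknown")
  expect_equal(cls$genus[4], "Halomonas")
})

test_that("screen_genome combines composition and taxonomy into evidence classes", {
  sim <- simulate_genome(n_background = 25, n_alien = 5,
                         len_codons_range = c(200, 300), seed = 13)
  hits <- simulate_hit_table(sim$truth, seed = 13)
  rep <- screen_genome(sim$genes, hits = hits)
  expect_equal(nrow(rep), 30)
  expect_true(all(rep$evidence_class %in%
                    c("both", "composition_only", "taxonomy_only", "none")))
  comp <- rep$rscu_flag | rep$gc_flag
  expect_equal(rep$evidence_class == "both" |
                 rep$evidence_class == "composition_only", comp)
  # without a hit table taxonomy-based classes are impossible
  rep0 <- screen_genome(sim$genes)
  expect_true(all(rep0$evidence_class %in% c("composition_only", "none")))
  # subset restricts reporting but keeps the full background
  sub <- screen_genome(sim$genes, subset = sim$genes$gene_id[1:4])
  expect_equal(nrow(sub), 4)
  full <- screen_genome(sim$genes)
  expect_equal(sub$n_changed, full$n_changed[1:4])
  expect_error(screen_genome(sim$genes, subset = "nope"), "nope")
})
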