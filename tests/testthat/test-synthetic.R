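code <- genetic_code()

test_that("profiles put the requested mass on G/C-ending codons", {
  p <- make_profile(1, alpha = 0)
  for (aa in names(p$families)) {
    fam <- p$families[[aa]]
    expect_equal(sum(fam), 1, tolerance = 1e-12)
    gc_end <- substring(names(fam), 3, 3) %in% c("G", "C")
    if (any(gc_end) && any(!gc_end)) expect_equal(sum(fam[gc_end]), 1)
  }
  # two-codon family with one G/C-ending codon at bias 0.5 -> (0.5, 0.5)
  p5 <- make_profile(0.5, alpha = 0)
  phe <- p5$families[["F"]]  # TTT / TTC
  expect_equal(unname(phe[order(names(phe))]), c(0.5, 0.5))
  expect_error(make_profile(1.2), "gc3_bias")
})

test_that("genes at gc3_bias 1 have synonymous GC3 exactly 1", {
  sim <- simulate_genome(n_background = 5, n_alien = 0,
                         len_codons_range = c(50, 80),
                         bg_profile = make_profile(1), seed = 3)
  for (s in sim$genes$sequence) {
    m <- gc_metrics(count_codons(s, code), code)
    expect_equal(m[["gc3_syn"]], 1)
  }
})

test_that("mean synonymous GC3 of simulated genes tracks the profile bias", {
  sim <- simulate_genome(n_background = 100, n_alien = 0,
                         len_codons_range = c(500, 500),
                         bg_profile = make_profile(0.8), seed = 12)
  gc3 <- vapply(sim$genes$sequence, function(s)
    gc_metrics(count_codons(s, code), code)[["gc3_syn"]], 0)
  # 3x the binomial standard error of one 500-codon gene's mean over 100 genes
  expect_lt(abs(mean(gc3) - 0.8), 0.03)
})

test_that("simulated genes are well-formed coding sequences", {
  sim <- simulate_genome(n_background = 20, n_alien = 5,
                         len_codons_range = c(30, 60), seed = 4)
  stops <- code$stop_codons
  for (s in sim$genes$sequence) {
    expect_equal(nchar(s) %% 3, 0)
    expect_identical(substring(s, 1, 3), "ATG")
    n3 <- nchar(s) / 3
    codons <- substring(s, 3 * (1:n3) - 2, 3 * (1:n3))
    expect_true(codons[n3] %in% stops)
    expect_false(any(codons[-n3] %in% stops))
  }
  expect_setequal(unique(sim$truth$origin), c("background", "alien"))
  expect_identical(sim$genes$gene_id, sim$truth$gene_id)
})

test_that("simulation is byte-identical under one seed and stable to appends", {
  a <- simulate_genome(30, 5, c(40, 60), seed = 99)
  b <- simulate_genome(30, 5, c(40, 60), seed = 99)
  expect_identical(a$genes, b$genes)
  # adding genes must not rewrite earlier genes' sequences
  bigger <- simulate_genome(30, 8, c(40, 60), seed = 99)
  expect_identical(bigger$genes$sequence[1:35], a$genes$sequence)
  # written FASTA is byte-identical too
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_genome(10, 2, c(30, 50), seed = 5, out_dir = d1)
  simulate_genome(10, 2, c(30, 50), seed = 5, out_dir = d2)
  expect_identical(readLines(file.path(d1, "genes.fasta")),
                   readLines(file.path(d2, "genes.fasta")))
  expect_error(simulate_genome(0, 0), "at least one")
  none <- simulate_genome(4, 0, c(30, 40), seed = 1)
  expect_true(all(none$truth$origin == "background"))
})

test_that("pooled codon usage converges to the generating profile", {
  prof <- make_profile(0.7)
  sim <- simulate_genome(n_background = 40, n_alien = 0,
                         len_codons_range = c(300, 300),
                         bg_profile = prof, seed = 21)
  pooled <- pool_background(sim$genes, code)$counts$counts
  # chi-square goodness of fit per family with expected mass >= 5
  for (aa in names(prof$families)) {
    fam <- prof$families[[aa]]
    if (length(fam) < 2) next
    obs <- pooled[names(fam)]
    if (sum(obs) < 100) next
    keep <- fam * sum(obs) >= 5
    if (sum(keep) < 2) next
    pval <- suppressWarnings(
      stats::chisq.test(obs[keep], p = fam[keep] / sum(fam[keep]))$p.value)
    expect_gt(pval, 0.01)
  }
})

test_that("alien recovery strengthens with profile divergence", {
  bg <- make_profile(0.85)
  rates <- vapply(c(0, 0.2, 0.4, 0.6), function(delta) {
    alien <- make_profile(0.85 - delta)
    sim <- simulate_genome(n_background = 60, n_alien = 10,
                           len_codons_range = c(200, 300),
                           bg_profile = bg, alien_profile = alien, seed = 31)
    rep <- screen_genome(sim$genes)
    mean(rep$rscu_flag[sim$truth$origin == "alien"])
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[4], rates[1])
})

test_that("simulated hit tables mirror truth labels deterministically", {
  truth <- data.frame(gene_id = sprintf("g%02d", 1:31),
                      origin = rep(c("alien", "background"), c(13, 18)))
  h1 <- simulate_hit_table(truth, seed = 6)
  h2 <- simulate_hit_table(truth, seed = 6)
  expect_identical(h1, h2)
  cls <- classify_hit(h1$organism)
  expect_equal(sum(cls$foreign_hit, na.rm = TRUE), 13)
  all_bg <- simulate_hit_table(transform(truth, origin = "background"),
                               self_organisms = "Halomonas lutea", seed = 2)
  expect_true(all(all_bg$organism == "Halomonas lutea"))
})
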