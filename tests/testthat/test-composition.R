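# Third-codon-position composition, genomic signature, deciles, gradients,
# nucleotide models, goodness-of-fit test.

test_that("codon_composition counts third positions with exclusions", {
  p <- codon_composition("ATGGCC")
  expect_equal(p$gc3, 1)
  expect_equal(p$C3 + p$G3, 2)

  p2 <- codon_composition("ATGAAA")
  expect_equal(p2$gc3, 0.5)

  p3 <- codon_composition("AAATTT")
  expect_equal(p3$gc3, 0)
  expect_true(is.na(p3$cg3_skew))

  # codon containing N is excluded; trailing partial codon ignored
  p4 <- codon_composition("ATGANAGGGTT")
  expect_equal(p4$n_codons, 2)
  expect_equal(p4$gc3, 1)          # ATG, GGG
  expect_equal(unname(is.na(p4$third_bases)), c(FALSE, TRUE, FALSE))

  expect_error(codon_composition("AT"), "shorter than one codon")

  # skew sign convention: C excess is positive
  expect_equal(codon_composition("AACAACAAG")$cg3_skew, 1 / 3)
})

test_that("gc3 and skew stay in bounds on random sequences", {
  set.seed(8)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 3 * sample(2:60, 1),
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    p <- tryCatch(codon_composition(s), error = function(e) NULL)
    if (is.null(p) || p$n_codons == 0) next
    expect_gte(p$gc3, 0); expect_lte(p$gc3, 1)
    if (!is.na(p$cg3_skew)) {
      expect_gte(p$cg3_skew, -1); expect_lte(p$cg3_skew, 1)
    }
  }
})

test_that("genomic signature matches hand counts and null expectation", {
  sig <- genomic_signature("CGCG")
  expect_equal(sig$rho_cg, 8 / 3)
  expect_equal(sig$f_cg, 2 / 3)

  expect_equal(genomic_signature("ATAT")$rho_cg, NA_real_)
  expect_equal(genomic_signature("CCGG")$rho_cg,
               (1 / 3) / (0.25))  # one CG in 3 windows
  expect_equal(genomic_signature("GGGCCC")$rho_cg, 0)  # no CG dinucleotide

  set.seed(12)
  s <- paste(sample(c("A", "C", "G", "T"), 1e6, replace = TRUE),
             collapse = "")
  expect_gt(genomic_signature(s)$rho_cg, 0.98)
  expect_lt(genomic_signature(s)$rho_cg, 1.02)
})

test_that("decile classification sizes, thresholds and tie-breaks", {
  tab <- data.frame(gene = sprintf("g%02d", 1:20), gc3 = (1:20) / 20)
  d <- classify_deciles(tab)
  expect_equal(d$n_per_class, 2)
  expect_setequal(d$rich, c("g19", "g20"))
  expect_equal(d$rich_threshold, 0.95)
  expect_setequal(d$poor, c("g01", "g02"))
  expect_equal(d$poor_threshold, 0.10)

  # all-equal GC3: sizes still exact, membership by id
  tab2 <- data.frame(gene = sprintf("g%02d", 1:20), gc3 = 0.5)
  d2 <- classify_deciles(tab2)
  expect_equal(d2$rich, c("g01", "g02"))
  expect_equal(d2$poor, c("g01", "g02"))

  # half-up rounding: 26,059 genes -> 2,606 per class
  expect_equal(floor(0.1 * 26059 + 0.5), 2606)
  expect_equal(classify_deciles(data.frame(gene = as.character(1:25),
                                           gc3 = runif(25)))$n_per_class, 3)
  expect_equal(classify_deciles(data.frame(gene = as.character(1:25),
                                           gc3 = runif(25)),
                                rounding = "floor")$n_per_class, 2)
  expect_error(classify_deciles(tab[1:5, ]), "at least 10")
})

test_that("positional gradients average only contributing genes", {
  profs <- list(codon_composition("ATGGGCGGC", "a"),   # 3 codons, all GC3
                codon_composition("ATGGGC", "b"))      # 2 codons
  gr <- positional_gradients(profs)
  expect_equal(gr$gc3$mean_value, c(1, 1, 1))
  expect_equal(gr$gc3$n_genes, c(2, 2, 1))
  # truncation beyond the longest gene is harmless
  gr2 <- positional_gradients(profs, max_codon = 10)
  expect_equal(nrow(gr2$gc3), 3)

  # skew at an index uses only C/G third bases
  profs2 <- list(codon_composition("AACAAT", "c"))  # third bases C, T
  gr3 <- positional_gradients(profs2)
  expect_equal(gr3$cg3_skew$mean_value, c(1, NA_real_))
})

test_that("gene-weighted gradient mean equals pooled GC3", {
  cfg <- sim_config(seed = 44, n_loci = 50)
  tr <- plant_gene_models(cfg, generate_genome(cfg))
  profs <- composition_profiles(tr$genome, tr$models)
  gr <- positional_gradients(profs)$gc3
  pooled_num <- sum(vapply(profs, function(p) p$C3 + p$G3, 0))
  pooled_den <- sum(vapply(profs, `[[`, 0L, "n_codons"))
  expect_equal(sum(gr$mean_value * gr$n_genes) / sum(gr$n_genes),
               pooled_num / pooled_den)
})

test_that("nucleotide models fit closed-form cases", {
  m <- fit_nucleotide_models("ACGT", kind = "multinomial")
  expect_equal(unname(m$probs), rep(0.25, 4))
  expect_equal(m$training_codons, 1)  # one complete codon used ("ACG")

  ps <- fit_nucleotide_models(c("ATG", "ATG", "CTG"),
                              kind = "position_specific")
  expect_equal(unname(ps$probs[1, ]), c(2 / 3, 1 / 3, 0, 0))
  expect_equal(unname(ps$probs[2, ]), c(0, 0, 0, 1))
  expect_equal(unname(ps$probs[3, ]), c(0, 0, 1, 0))
  expect_true(all(abs(rowSums(ps$probs) - 1) < 1e-12))

  mk <- fit_nucleotide_models(strrep("A", 30), kind = "markov3")
  for (pos in 1:3) expect_equal(mk$probs[[pos]]["A", "A"], 1)

  expect_error(fit_nucleotide_models("NNN", kind = "multinomial"),
               "no complete N-free codon")
})

test_that("markov3 fit recovers known transition matrices", {
  trans <- list(
    matrix(c(.7, .1, .1, .1,  .1, .7, .1, .1,
             .1, .1, .7, .1,  .1, .1, .1, .7), 4, 4, byrow = TRUE,
           dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))),
    matrix(.25, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"))),
    matrix(c(.4, .3, .2, .1,  .1, .4, .3, .2,
             .2, .1, .4, .3,  .3, .2, .1, .4), 4, 4, byrow = TRUE,
           dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  )
  set.seed(99)
  cds <- sample_markov3_cds(trans, 20000)
  fit <- fit_nucleotide_models(cds, kind = "markov3")
  for (pos in 1:3)
    expect_lt(max(abs(fit$probs[[pos]] - trans[[pos]])), 0.03)
})

test_that("markov3 beats multinomial on held-out Markov data", {
  trans <- list(
    matrix(c(.6, .2, .1, .1,  .1, .6, .2, .1,
             .1, .1, .6, .2,  .2, .1, .1, .6), 4, 4, byrow = TRUE),
    matrix(c(.1, .4, .4, .1,  .4, .1, .1, .4,
             .25, .25, .25, .25, .1, .1, .4, .4), 4, 4, byrow = TRUE),
    matrix(.25, 4, 4)
  )
  trans <- lapply(trans, function(m) {
    dimnames(m) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T")); m
  })
  set.seed(7)
  wins <- 0L
  for (r in 1:5) {
    train <- sample_markov3_cds(trans, 5000)
    test <- sample_markov3_cds(trans, 5000)
    mk <- fit_nucleotide_models(train, kind = "markov3", smoothing = 0.5)
    mn <- fit_nucleotide_models(train, kind = "multinomial", smoothing = 0.5)
    if (loglik_nucleotide_model(mk, test) >
        loglik_nucleotide_model(mn, test)) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})

test_that("goodness-of-fit test matches hand-computed chi-squared", {
  r <- enrichment_test(10, 30)
  expect_equal(r$chi_squared, 10)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, 1.565402e-3, tolerance = 1e-6)

  r0 <- enrichment_test(20, 20)
  expect_equal(r0$chi_squared, 0)
  expect_equal(r0$p_value, 1)

  expect_error(enrichment_test(c(a = 0, b = 5), c(a = 0, b = 5)),
               "category 'a'")

  # background weights shift the expectation
  r2 <- enrichment_test(30, 10, background_rich = 3, background_poor = 1)
  expect_equal(r2$chi_squared, 0)
})

test_that("chi-squared p-values agree with the integration oracle", {
  set.seed(13)
  for (i in 1:25) {
    o <- sample(5:60, 2)
    r <- enrichment_test(o[1], o[2])
    expect_equal(r$p_value, chisq_upper_oracle(r$chi_squared, 1),
                 tolerance = 1e-9)
  }
})
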