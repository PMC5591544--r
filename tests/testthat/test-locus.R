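# Locus integration: overlap statistic, single-linkage clustering, the
# threshold sweep, evidence filters, representative selection, contaminant
# removal.

span_model <- function(id, start, end, scaffold = "s1", strand = "+",
                       source = "A") {
  gene_model(id, source, scaffold, strand, cbind(start, end))
}

test_that("overlap_fraction is shared length over the shorter span", {
  a <- span_model("a", 100, 400)
  b <- span_model("b", 250, 550)
  expect_equal(overlap_fraction(a, b), 0.5)
  expect_equal(overlap_fraction(a, a), 1)
  expect_equal(overlap_fraction(a, span_model("c", 600, 900)), 0)
  expect_equal(overlap_fraction(a, span_model("d", 100, 400, strand = "-")), 0)
  expect_equal(overlap_fraction(a, span_model("e", 100, 400,
                                              scaffold = "s2")), 0)
  # nested: intersection equals the shorter span
  expect_equal(overlap_fraction(a, span_model("f", 150, 250)), 1)
})

test_that("single-linkage chains merge or break with the threshold", {
  # A-B overlap 0.9, B-C overlap 0.9, A-C overlap ~0.1
  a <- span_model("a", 0, 1000)
  b <- span_model("b", 100, 1100)
  c <- span_model("c", 200, 1200)
  expect_gte(overlap_fraction(a, b), 0.9)
  expect_gte(overlap_fraction(b, c), 0.9)
  expect_lt(overlap_fraction(a, c), 0.85)
  one <- cluster_loci(list(a, b, c), 0.85)
  expect_length(one, 1)
  expect_setequal(one[[1]]$members, c("a", "b", "c"))
  three <- cluster_loci(list(a, b, c), 0.95)
  expect_length(three, 3)
})

test_that("predictions shorter than the ORF cutoff are excluded", {
  short <- span_model("short", 0, 299)
  exact <- span_model("exact", 1000, 1300)
  loci <- cluster_loci(list(short, exact), 0.85)
  expect_length(loci, 1)
  expect_equal(loci[[1]]$members, "exact")
})

test_that("clustering equals the brute-force union-find oracle", {
  set.seed(2024)
  for (i in 1:200) {
    models <- random_models(sample(2:30, 1))
    threshold <- sample(seq(0.6, 0.95, 0.05), 1)
    loci <- cluster_loci(models, threshold)
    got <- canonical_partition(lapply(loci, `[[`, "members"))
    want <- canonical_partition(oracle_partition(models, threshold))
    expect_identical(got, want)
  }
})

test_that("every retained model lands in exactly one locus", {
  set.seed(91)
  models <- random_models(60)
  loci <- cluster_loci(models, 0.7)
  members <- unlist(lapply(loci, `[[`, "members"))
  kept <- model_table(models)
  kept <- kept$id[kept$cds_length >= 300]
  expect_setequal(members, kept)
  expect_equal(anyDuplicated(members), 0)
  for (l in loci) {
    tab <- model_table(models)
    sub <- tab[tab$id %in% l$members, ]
    expect_equal(unique(sub$scaffold), l$scaffold)
    expect_equal(unique(sub$strand), l$strand)
  }
})

test_that("locus count is non-decreasing in the threshold", {
  set.seed(17)
  for (i in 1:20) {
    models <- random_models(40, span_max = 3000)
    sw <- sweep_and_select(models)$sweep
    expect_true(all(diff(sw$n_loci) >= 0))
  }
})

test_that("identical prediction sets flag the sweep selection undefined", {
  set.seed(3)
  base <- lapply(1:20, function(i)
    span_model(sprintf("g%02d", i), i * 3000L, i * 3000L + 1000L))
  dup <- lapply(base, function(m)
    gene_model(paste0(m$id, "_B"), "B", m$scaffold, m$strand, m$segments))
  sw <- sweep_and_select(c(base, dup))
  expect_true(all(sw$sweep$n_loci == sw$sweep$n_loci[1]))
  expect_true(is.na(sw$selected_threshold))
})

test_that("pairwise overlaps planted in (0.85, 0.95) select threshold 0.85", {
  set.seed(4)
  models <- list()
  for (i in 1:40) {
    len <- 1000L
    start <- i * 5000L
    ov <- runif(1, 0.86, 0.94)
    shift <- as.integer(round((1 - ov) * len))
    models[[2 * i - 1]] <- span_model(sprintf("a%02d", i), start, start + len)
    models[[2 * i]] <- span_model(sprintf("b%02d", i), start + shift,
                                  start + shift + len, source = "B")
  }
  sw <- sweep_and_select(models)
  expect_equal(sw$selected_threshold, 0.85)
})

test_that("evidence filter enforces all thresholds conjunctively", {
  m <- list(span_model("g1", 0, 500))
  hit <- function(db, id = 60, score = 150, qc = 85, sc = 90, e = 1e-30) {
    data.frame(query = "g1", subject = "x", description = "kinase",
               database = db, e_value = e, bit_score = score,
               pct_identity = id, query_cov = qc, subject_cov = sc,
               stringsAsFactors = FALSE)
  }
  good <- rbind(hit("refseq_plant"), hit("mrna", id = 95))
  expect_length(evidence_filter(m, good), 1)
  expect_length(evidence_filter(m, rbind(hit("refseq_plant", id = 40),
                                         hit("mrna", id = 95))), 0)
  expect_length(evidence_filter(m, rbind(hit("refseq_plant", score = 99),
                                         hit("mrna", id = 95))), 0)
  expect_length(evidence_filter(m, rbind(hit("refseq_plant", qc = 79),
                                         hit("mrna", id = 95))), 0)
  expect_length(evidence_filter(m, rbind(hit("refseq_plant", sc = 79),
                                         hit("mrna", id = 95))), 0)
  # transcript identity of exactly 90 fails the strict > 90 rule
  expect_length(evidence_filter(m, rbind(hit("refseq_plant"),
                                         hit("mrna", id = 90))), 0)
  expect_length(evidence_filter(m, hit("refseq_plant")), 0)
  expect_length(evidence_filter(m, hit("refseq_plant"), mode = "union"), 1)
})

test_that("representative selection follows E-value with blacklist", {
  locus <- cluster_loci(list(span_model("g1", 0, 500),
                             span_model("g2", 10, 510)), 0.85)[[1]]
  hits <- data.frame(
    query = c("g1", "g2"), subject = c("P1", "P2"),
    description = c("cellulose synthase", "MYB factor"),
    database = "refseq_plant",
    e_value = c(1e-20, 1e-50), bit_score = c(100, 200),
    pct_identity = 80, query_cov = 90, subject_cov = 90,
    stringsAsFactors = FALSE)
  sel <- select_representative(locus, hits)
  expect_equal(sel$representative, "g2")
  expect_equal(sel$annotation$e_value, 1e-50)

  hits$description <- "Hypothetical protein X"
  expect_null(select_representative(locus, hits))

  hits$description <- "cellulose synthase"
  hits$e_value <- c(1e-9, 1e-9)
  expect_null(select_representative(locus, hits))

  # tie on E-value -> higher bit score wins; tie on both -> lexicographic id
  hits$e_value <- 1e-30
  expect_equal(select_representative(locus, hits)$representative, "g2")
  hits$bit_score <- 100
  expect_equal(select_representative(locus, hits)$representative, "g1")
})

test_that("contaminant scaffolds are removed only without any support", {
  loci <- list(
    cluster_loci(list(span_model("g1", 0, 500, scaffold = "bad")), 0.85)[[1]],
    cluster_loci(list(span_model("g2", 0, 500, scaffold = "ok")), 0.85)[[1]],
    cluster_loci(list(span_model("g3", 0, 500, scaffold = "plant")), 0.85)[[1]]
  )
  tax <- data.frame(
    scaffold = c("bad", "ok", "plant"),
    best_hit = c("bacterial", "bacterial", "plant_nuclear"),
    support_sister = c(FALSE, FALSE, FALSE),
    support_transcriptome = c(FALSE, TRUE, FALSE),
    support_newer = c(FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  kept <- filter_contaminant_scaffolds(loci, tax)
  expect_setequal(vapply(kept, `[[`, "", "scaffold"), c("ok", "plant"))
  # scaffold missing from the table is treated as plant nuclear
  loci2 <- list(cluster_loci(list(span_model("g4", 0, 400,
                                             scaffold = "unseen")), 0.85)[[1]])
  expect_length(filter_contaminant_scaffolds(loci2, tax), 1)
})

test_that("zero-perturbation merge recovers the planted locus count", {
  cfg <- sim_config(seed = 31, n_loci = 25)
  tr <- plant_gene_models(cfg, generate_genome(cfg))
  pr <- emulate_pipelines(tr, cfg)
  models <- c(pr$pipelines[[1]], pr$pipelines[[2]])
  for (t in seq(0.6, 0.95, 0.05))
    expect_length(cluster_loci(models, t), 25)
  hits <- synthesize_hits(models, cfg)
  mg <- merge_predictions(pr$pipelines, hits, threshold = 0.85)
  expect_length(mg$loci, 25)
  expect_true(all(vapply(mg$loci, function(l) !is.null(l$representative), NA)))
})

test_that("merged GFF3 output is deterministic and annotated", {
  cfg <- sim_config(seed = 31, n_loci = 10)
  tr <- plant_gene_models(cfg, generate_genome(cfg))
  pr <- emulate_pipelines(tr, cfg)
  models <- c(pr$pipelines[[1]], pr$pipelines[[2]])
  hits <- synthesize_hits(models, cfg)
  mg <- merge_predictions(pr$pipelines, hits, threshold = 0.85)
  f1 <- withr::local_tempfile(fileext = ".gff3")
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_merged_gff3(mg, f1)
  write_merged_gff3(mg, f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_true(any(grepl("locus_id=", lines)))
  expect_true(any(grepl("representative=true", lines)))
  expect_length(read_gff3(f1), length(mg$locus_of))
})
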