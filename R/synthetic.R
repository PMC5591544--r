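# Synthetic annotation projects with planted ground truth: background
# genome, planted ORFs with controlled third-codon-position composition,
# two perturbed prediction sets, and mock evidence tables. Every generator
# is a pure function of (config, seed); each draws from its own named
# sub-stream of the global seed so adding a generator never shifts the
# streams of existing ones.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generators.
#' Defaults emulate a desk-scale plant annotation project: a handful of
#' 200-kb scaffolds at 37% background GC, a few hundred planted loci with
#' the empirical exon-count mix of a palm-like genome (14% mono-exonic, 16%
#' two-exon, mean around four exons), CDS lengths of 300-3000 nt, per-gene
#' GC3 targets spread broadly over 0.30-0.90, and unperturbed prediction
#' copies (jitter/split/drop all zero) unless asked otherwise.
#'
#' @param seed Integer global seed; every generator derives a named
#'   sub-stream from it.
#' @param n_scaffolds,scaffold_length Number and length (nt) of scaffolds.
#' @param background_gc Background GC fraction of intergenic sequence.
#' @param n_loci Number of planted gene loci.
#' @param exon_count_probs Named probability vector over exon counts
#'   (names are the counts); must sum to 1.
#' @param intron_length_range,cds_length_range Integer pairs (nt); CDS
#'   lengths are rounded to multiples of 3.
#' @param gc3_range Per-gene target GC3 is drawn uniformly from this range.
#' @param gc3_slope Linear per-codon gradient added to the target GC3,
#'   centered on the middle codon of each gene.
#' @param jitter_sd Gaussian SD (nt) for boundary perturbation in
#'   [emulate_pipelines()].
#' @param split_rate,drop_rate,spurious_rate Per-model probabilities that an
#'   emulated pipeline splits a true model in two, drops it, or adds an
#'   unmatched (spurious) model.
#' @param refseq_fail_rate,mrna_fail_rate,blacklist_rate Rates at which
#'   [synthesize_hits()] emits failing protein evidence, failing transcript
#'   evidence, or blacklist-worded descriptions.
#' @param kingdom_profile Character vector of kingdom/group database tags
#'   every model receives a hit from in [synthesize_hits()].
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 5L,
                       scaffold_length = 200000L,
                       background_gc = 0.37,
                       n_loci = 200L,
                       exon_count_probs = c("1" = 0.14, "2" = 0.16,
                                            "3" = 0.15, "4" = 0.13,
                                            "5" = 0.11, "6" = 0.09,
                                            "7" = 0.07, "8" = 0.06,
                                            "9" = 0.05, "10" = 0.04),
                       intron_length_range = c(100L, 1000L),
                       cds_length_range = c(300L, 3000L),
                       gc3_range = c(0.30, 0.90),
                       gc3_slope = 0,
                       jitter_sd = 0,
                       split_rate = 0,
                       drop_rate = 0,
                       spurious_rate = 0,
                       refseq_fail_rate = 0,
                       mrna_fail_rate = 0,
                       blacklist_rate = 0,
                       kingdom_profile = "viridiplantae") {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_scaffolds >= 1L, scaffold_length >= 1L,
            background_gc >= 0, background_gc <= 1,
            n_loci >= 0L,
            all(exon_count_probs >= 0),
            length(intron_length_range) == 2L,
            intron_length_range[1L] <= intron_length_range[2L],
            intron_length_range[1L] >= 1L,
            length(cds_length_range) == 2L,
            cds_length_range[1L] <= cds_length_range[2L],
            cds_length_range[1L] >= 3L,
            length(gc3_range) == 2L, gc3_range[1L] <= gc3_range[2L],
            gc3_range[1L] >= 0, gc3_range[2L] <= 1,
            jitter_sd >= 0,
            split_rate >= 0, split_rate <= 1,
            drop_rate >= 0, drop_rate <= 1,
            spurious_rate >= 0, spurious_rate <= 1,
            refseq_fail_rate >= 0, refseq_fail_rate <= 1,
            mrna_fail_rate >= 0, mrna_fail_rate <= 1,
            blacklist_rate >= 0, blacklist_rate <= 1,
            all(kingdom_profile %in% c("archaea", "bacteria", "eukaryote",
                                       "viridiplantae", "fungi", "metazoa")))
  if (abs(sum(exon_count_probs) - 1) > 1e-8)
    stop("exon_count_probs must sum to 1")
  if (is.null(names(exon_count_probs)) ||
      anyNA(suppressWarnings(as.integer(names(exon_count_probs)))))
    stop("exon_count_probs must be named by integer exon counts")
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_length = as.integer(scaffold_length),
              background_gc = background_gc, n_loci = as.integer(n_loci),
              exon_count_probs = exon_count_probs,
              intron_length_range = as.integer(intron_length_range),
              cds_length_range = as.integer(cds_length_range),
              gc3_range = gc3_range, gc3_slope = gc3_slope,
              jitter_sd = jitter_sd, split_rate = split_rate,
              drop_rate = drop_rate, spurious_rate = spurious_rate,
              refseq_fail_rate = refseq_fail_rate,
              mrna_fail_rate = mrna_fail_rate,
              blacklist_rate = blacklist_rate,
              kingdom_profile = kingdom_profile)
  class(cfg) <- "sim_config"
  cfg
}

# sample n integers uniformly from [a, b]; safe when a == b (avoids the
# base-R sample() scalar expansion)
sample_range <- function(a, b, n) {
  if (a == b) rep(as.integer(a), n) else sample(seq.int(a, b), n, replace = TRUE)
}

# named sub-stream seed: stable under addition of new streams
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 1009L + h %% 1000003L
}

#' Generate a background genome
#'
#' I.i.d. sequence at the configured GC fraction, one scaffold per record.
#' Identical config (including seed) gives identical sequence.
#'
#' @param config A [sim_config()].
#' @return Named character vector of scaffold sequences.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "genome"))
  p <- c(A = (1 - config$background_gc) / 2, C = config$background_gc / 2,
         G = config$background_gc / 2, T = (1 - config$background_gc) / 2)
  seqs <- vapply(seq_len(config$n_scaffolds), function(i) {
    paste(sample(names(p), config$scaffold_length, replace = TRUE, prob = p),
          collapse = "")
  }, "")
  names(seqs) <- sprintf("scaffold_%04d", seq_len(config$n_scaffolds))
  seqs
}

# one coding sequence honoring a planted GC3 profile: ATG start, single
# terminal stop, no internal in-frame stop; third-base G/C drawn per codon
# with probability gc3_target + slope * (codon index - center)
synth_cds <- function(n_codons, gc3_target, gc3_slope) {
  stopifnot(n_codons >= 2L)
  k <- seq_len(n_codons)
  p <- pmin(1, pmax(0, gc3_target + gc3_slope * (k - (n_codons + 1) / 2)))
  third_gc <- stats::runif(n_codons) < p
  first <- sample(c("A", "C", "G", "T"), n_codons, replace = TRUE)
  second <- sample(c("A", "C", "G", "T"), n_codons, replace = TRUE)
  third <- ifelse(third_gc, sample(c("G", "C"), n_codons, replace = TRUE),
                  sample(c("A", "T"), n_codons, replace = TRUE))
  # avoid internal stops TAA/TAG/TGA: rewrite offending third bases within
  # their planted GC class (TAA->TAT, TAG->TAC, TGA->TGT/TGC)
  ta <- first == "T" & second == "A"
  third[ta & third == "A"] <- "T"
  third[ta & third == "G"] <- "C"
  tga <- first == "T" & second == "G" & third == "A"
  third[tga] <- "T"
  codons <- paste0(first, second, third)
  codons[1L] <- "ATG"
  codons[n_codons] <- if (third_gc[n_codons]) "TAG" else "TAA"
  paste(codons, collapse = "")
}

#' Plant gene models into a background genome
#'
#' Lays out `n_loci` non-overlapping gene loci across the scaffolds, writes a
#' valid ORF into the genome at each locus (ATG start, single terminal stop,
#' length a multiple of 3, no internal in-frame stop) whose third-codon-position
#' composition follows the planted per-gene GC3 target and per-codon gradient
#' slope, and records the ground truth.
#'
#' @param config A [sim_config()].
#' @param genome Named character vector from [generate_genome()].
#' @return List of class `synthetic_truth` with elements `genome` (edited
#'   sequences), `models` (list of [gene_model()]s, source `"truth"`),
#'   `locus_of` (named map model id -> locus id), `gc3` (named planted
#'   per-gene GC3 targets) and `config`.
#' @export
plant_gene_models <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "plant"))
  n <- config$n_loci
  ks <- as.integer(sample(names(config$exon_count_probs), n, replace = TRUE,
                          prob = config$exon_count_probs))
  lens <- sample_range(config$cds_length_range[1L],
                       config$cds_length_range[2L], n)
  lens <- pmax(6L, (lens %/% 3L) * 3L)
  gc3 <- stats::runif(n, config$gc3_range[1L], config$gc3_range[2L])
  strands <- sample(c("+", "-"), n, replace = TRUE)
  min_exon <- 30L
  ks <- pmin(ks, pmax(1L, lens %/% min_exon))  # every exon at least min_exon

  models <- vector("list", n)
  locus_of <- character(n)
  scaffold_i <- 1L
  cursor <- 0L
  for (g in seq_len(n)) {
    k <- ks[g]
    L <- lens[g]
    # exon lengths: min_exon each plus random split of the remainder
    extra <- L - k * min_exon
    cuts <- if (k > 1L) sort(sample.int(extra + 1L, k - 1L, replace = TRUE) - 1L)
            else integer(0)
    exon_len <- diff(c(0L, cuts, extra)) + min_exon
    intron_len <- if (k > 1L)
      sample_range(config$intron_length_range[1L],
                   config$intron_length_range[2L], k - 1L)
      else integer(0)
    gap <- sample(200:2000, 1L)
    span <- sum(exon_len) + sum(intron_len)
    if (cursor + gap + span > config$scaffold_length) {
      scaffold_i <- scaffold_i + 1L
      cursor <- 0L
      if (scaffold_i > config$n_scaffolds)
        stop("insufficient scaffold space to plant ", n, " loci; ",
             "increase scaffold_length or n_scaffolds")
    }
    start <- cursor + gap
    starts <- start + cumsum(c(0L, (exon_len + c(intron_len, 0L))[-k]))
    segments <- cbind(starts, starts + exon_len)
    id <- sprintf("tg%04d", g)
    scaf <- names(genome)[scaffold_i]
    m <- gene_model(id, "truth", scaf, strands[g], segments)
    cds <- synth_cds(L %/% 3L, gc3[g], config$gc3_slope)
    forward <- if (strands[g] == "-") revcomp(cds) else cds
    # write the CDS across the segments in ascending genomic order
    off <- 0L
    s <- genome[[scaf]]
    for (e in seq_len(k)) {
      w <- exon_len[e]
      substr(s, segments[e, 1L] + 1L, segments[e, 2L]) <-
        substr(forward, off + 1L, off + w)
      off <- off + w
    }
    genome[[scaf]] <- s
    models[[g]] <- m
    locus_of[g] <- sprintf("truelocus%04d", g)
    cursor <- start + span
  }
  names(locus_of) <- vapply(models, `[[`, "", "id")
  names(gc3) <- names(locus_of)
  structure(list(genome = genome, models = models, locus_of = locus_of,
                 gc3 = gc3, config = config),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d planted loci on %d scaffold(s)\n",
              length(x$models), length(x$genome)))
  invisible(x)
}

jitter_model <- function(m, sd, scaffold_len, new_id, label) {
  seg <- m$segments
  if (sd > 0) {
    d <- as.integer(round(stats::rnorm(2L, 0, sd)))
    k <- nrow(seg)
    new_start <- max(0L, min(seg[1L, 2L] - 1L, seg[1L, 1L] + d[1L]))
    floor_end <- if (k == 1L) new_start + 1L else seg[k, 1L] + 1L
    new_end <- min(scaffold_len, max(floor_end, seg[k, 2L] + d[2L]))
    seg[1L, 1L] <- new_start
    seg[k, 2L] <- new_end
  }
  gene_model(new_id, label, m$scaffold, m$strand, seg)
}

#' Emulate two prediction pipelines over the planted truth
#'
#' Each pipeline receives a perturbed copy of every true model: outer
#' boundaries jittered by rounded Gaussian noise (`jitter_sd`), the model
#' split in two with probability `split_rate`, or dropped with probability
#' `drop_rate`. Optionally spurious models with no true counterpart are
#' added at rate `spurious_rate`. Provenance from every emitted model back
#' to its true locus (or `"spurious"`) is retained.
#'
#' @param truth A `synthetic_truth` from [plant_gene_models()].
#' @param config A [sim_config()]; perturbation rates are read from here.
#' @param labels Length-2 character vector of pipeline source labels.
#' @return List of class `emulated_predictions` with elements `pipelines`
#'   (list of two model lists) and `provenance` (named map emitted model id
#'   -> true locus id or `"spurious"`).
#' @export
emulate_pipelines <- function(truth, config = truth$config,
                              labels = c("pipelineA", "pipelineB")) {
  stopifnot(inherits(truth, "synthetic_truth"), length(labels) == 2L)
  set.seed(substream_seed(config$seed, "pipelines"))
  provenance <- character(0)
  pipelines <- vector("list", 2L)
  names(pipelines) <- labels
  for (p in 1:2) {
    out <- list()
    for (m in truth$models) {
      if (stats::runif(1) < config$drop_rate) next
      locus <- truth$locus_of[[m$id]]
      base_id <- paste0(m$id, "_", labels[p])
      mm <- jitter_model(m, config$jitter_sd, config$scaffold_length,
                         base_id, labels[p])
      if (stats::runif(1) < config$split_rate && cds_length(mm) >= 60L) {
        seg <- mm$segments
        k <- nrow(seg)
        if (k >= 2L) {
          cut <- k %/% 2L
          parts <- list(seg[seq_len(cut), , drop = FALSE],
                        seg[(cut + 1L):k, , drop = FALSE])
        } else {
          mid <- as.integer((seg[1L, 1L] + seg[1L, 2L]) %/% 2L)
          parts <- list(cbind(seg[1L, 1L], mid), cbind(mid, seg[1L, 2L]))
        }
        for (j in 1:2) {
          id <- paste0(base_id, letters[j])
          out[[id]] <- gene_model(id, labels[p], mm$scaffold, mm$strand,
                                  parts[[j]])
          provenance[id] <- locus
        }
      } else {
        out[[base_id]] <- mm
        provenance[base_id] <- locus
      }
    }
    n_spur <- stats::rbinom(1L, length(truth$models), config$spurious_rate)
    if (n_spur > 0L) {
      occupied <- model_table(truth$models)
      for (s in seq_len(n_spur)) {
        scaf <- sample(names(truth$genome), 1L)
        len <- sample(300:900, 1L)
        len <- (len %/% 3L) * 3L
        for (try in 1:50) {
          st <- sample.int(config$scaffold_length - len, 1L) - 1L
          occ <- occupied[occupied$scaffold == scaf, , drop = FALSE]
          if (!any(st < occ$end & st + len > occ$start)) break
          st <- NA_integer_
        }
        if (is.na(st)) next
        id <- sprintf("spur%03d_%s", s, labels[p])
        out[[id]] <- gene_model(id, labels[p], scaf,
                                sample(c("+", "-"), 1L), cbind(st, st + len))
        provenance[id] <- "spurious"
      }
    }
    pipelines[[p]] <- unname(out)
  }
  structure(list(pipelines = pipelines, provenance = provenance),
            class = "emulated_predictions")
}

BLACKLIST_DESCRIPTIONS <- c("hypothetical protein", "predicted protein",
                            "putative protein", "unnamed protein product",
                            "uncharacterized protein")
CLEAN_DESCRIPTIONS <- c("serine/threonine-protein kinase", "MYB transcription factor",
                        "cellulose synthase", "ATP-dependent RNA helicase",
                        "chlorophyll a-b binding protein", "ubiquitin ligase")

#' Synthesize homology-evidence hits for a model set
#'
#' Emits one protein (refseq_plant) and one transcript (mrna) hit per model,
#' passing the downstream evidence thresholds except for configurable failure
#' fractions, plus one hit per kingdom/group tag in the config's
#' `kingdom_profile`. A `blacklist_rate` fraction of refseq descriptions use
#' blacklist wording ("hypothetical protein" etc.), which later disqualifies
#' the locus during representative selection.
#'
#' @param models List of [gene_model()]s.
#' @param config A [sim_config()].
#' @return `data.frame` in [read_homology_hits()] layout.
#' @export
synthesize_hits <- function(models, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "hits"))
  tab <- model_table(models)
  n <- nrow(tab)
  if (n == 0L)
    return(data.frame(query = character(), subject = character(),
                      description = character(), database = character(),
                      e_value = numeric(), bit_score = numeric(),
                      pct_identity = numeric(), query_cov = numeric(),
                      subject_cov = numeric(), stringsAsFactors = FALSE))
  refseq_fail <- stats::runif(n) < config$refseq_fail_rate
  mrna_fail <- stats::runif(n) < config$mrna_fail_rate
  blacklisted <- stats::runif(n) < config$blacklist_rate
  desc <- ifelse(blacklisted,
                 sample(BLACKLIST_DESCRIPTIONS, n, replace = TRUE),
                 sample(CLEAN_DESCRIPTIONS, n, replace = TRUE))
  refseq <- data.frame(
    query = tab$id,
    subject = sprintf("XP_%06d", seq_len(n)),
    description = desc,
    database = "refseq_plant",
    e_value = 10 ^ stats::runif(n, -60, -20),
    bit_score = ifelse(refseq_fail, stats::runif(n, 20, 90),
                       stats::runif(n, 120, 800)),
    pct_identity = ifelse(refseq_fail, stats::runif(n, 10, 45),
                          stats::runif(n, 55, 95)),
    query_cov = stats::runif(n, 85, 100),
    subject_cov = stats::runif(n, 85, 100),
    stringsAsFactors = FALSE
  )
  mrna <- data.frame(
    query = tab$id,
    subject = sprintf("mrna_%06d", seq_len(n)),
    description = "transcript",
    database = "mrna",
    e_value = 10 ^ stats::runif(n, -80, -30),
    bit_score = stats::runif(n, 200, 2000),
    pct_identity = ifelse(mrna_fail, stats::runif(n, 50, 90),
                          stats::runif(n, 90.5, 100)),
    query_cov = stats::runif(n, 90, 100),
    subject_cov = stats::runif(n, 90, 100),
    stringsAsFactors = FALSE
  )
  kingdoms <- do.call(rbind, lapply(config$kingdom_profile, function(db) {
    data.frame(query = tab$id,
               subject = sprintf("%s_%06d", db, seq_len(n)),
               description = "conserved protein",
               database = db,
               e_value = 10 ^ stats::runif(n, -40, -10),
               bit_score = stats::runif(n, 100, 500),
               pct_identity = stats::runif(n, 40, 90),
               query_cov = stats::runif(n, 60, 100),
               subject_cov = stats::runif(n, 60, 100),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(refseq, mrna, kingdoms)
  rownames(out) <- NULL
  out
}

R_CLASS_DOMAINS <- list(
  CNL = c("CC", "NBS", "LRR"),
  TNL = c("TIR", "NBS", "LRR"),
  Kinase = "STK",
  RLP = c("TM", "LRR"),
  RLK = c("TM", "LRR", "STK"),
  `Mlo-like` = "MLO"
)

#' Synthesize protein-domain architectures and TM-helix counts
#'
#' Plants the six resistance-gene class architectures on a chosen number of
#' models: CNL = CC+NBS+LRR, TNL = TIR+NBS+LRR, Kinase = STK, RLP = TM+LRR,
#' RLK = TM+LRR+STK, Mlo-like = MLO with 6 or 7 transmembrane helices.
#' Remaining models receive an OTHER domain or none, and zero TM helices.
#'
#' @param models List of [gene_model()]s.
#' @param config A [sim_config()].
#' @param class_counts Named integer vector of planted class sizes; names
#'   from `CNL, TNL, Kinase, RLP, RLK, Mlo-like`. The default plants the
#'   class mixture of a palm-scale resistance-gene survey.
#' @return List with `domains` and `tm` data frames (layouts of
#'   [read_domain_hits()] / [read_tm_records()]) and `classes`, the named
#'   planted class per selected model id.
#' @export
synthesize_domains <- function(models, config,
                               class_counts = c(CNL = 141L, TNL = 0L,
                                                Kinase = 7L, RLP = 3L,
                                                RLK = 3L, `Mlo-like` = 13L)) {
  stopifnot(inherits(config, "sim_config"),
            all(names(class_counts) %in% names(R_CLASS_DOMAINS)),
            all(class_counts >= 0L))
  tab <- model_table(models)
  if (sum(class_counts) > nrow(tab))
    stop("class_counts sum (", sum(class_counts), ") exceeds number of ",
         "models (", nrow(tab), ")")
  set.seed(substream_seed(config$seed, "domains"))
  picked <- sample(tab$id, sum(class_counts))
  classes <- rep(names(class_counts), class_counts)
  names(classes) <- picked
  rows <- lapply(picked, function(id) {
    data.frame(gene = id, domain = R_CLASS_DOMAINS[[classes[[id]]]],
               stringsAsFactors = FALSE)
  })
  rest <- setdiff(tab$id, picked)
  rest_dom <- rest[stats::runif(length(rest)) < 0.5]
  if (length(rest_dom) > 0L)
    rows <- c(rows, list(data.frame(gene = rest_dom, domain = "OTHER",
                                    stringsAsFactors = FALSE)))
  domains <- do.call(rbind, rows)
  rownames(domains) <- NULL
  tm <- data.frame(gene = tab$id, tm_helices = 0L, stringsAsFactors = FALSE)
  is_mlo <- tab$id %in% picked[classes == "Mlo-like"]
  tm$tm_helices[is_mlo] <- sample(6:7, sum(is_mlo), replace = TRUE)
  is_memb <- tab$id %in% picked[classes %in% c("RLP", "RLK")]
  tm$tm_helices[is_memb] <- 1L
  list(domains = domains, tm = tm, classes = classes)
}

#' Write a complete synthetic dataset to disk
#'
#' Convenience wrapper running every generator and writing the standard
#' files: `genome.fasta`, `truth.gff3`, `pipelineA.gff3`, `pipelineB.gff3`,
#' `hits.tsv`, `domains.tsv`, `tm.tsv`, `taxonomy.tsv`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory `truth`, `predictions`,
#'   `hits`, `domains` and file paths.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(config)
  truth <- plant_gene_models(config, genome)
  preds <- emulate_pipelines(truth, config)
  all_models <- c(preds$pipelines[[1L]], preds$pipelines[[2L]])
  hits <- synthesize_hits(all_models, config)
  dom <- synthesize_domains(truth$models, config,
                            class_counts = c(CNL = min(10L, config$n_loci)))
  taxonomy <- data.frame(scaffold = names(truth$genome),
                         best_hit = "plant_nuclear",
                         support_sister = TRUE,
                         support_transcriptome = TRUE,
                         support_newer = TRUE, stringsAsFactors = FALSE)
  paths <- list(
    genome = file.path(out_dir, "genome.fasta"),
    truth = file.path(out_dir, "truth.gff3"),
    pipelineA = file.path(out_dir, "pipelineA.gff3"),
    pipelineB = file.path(out_dir, "pipelineB.gff3"),
    hits = file.path(out_dir, "hits.tsv"),
    domains = file.path(out_dir, "domains.tsv"),
    tm = file.path(out_dir, "tm.tsv"),
    taxonomy = file.path(out_dir, "taxonomy.tsv")
  )
  write_fasta(truth$genome, paths$genome)
  write_gff3(truth$models, paths$truth, locus_of = truth$locus_of)
  write_gff3(preds$pipelines[[1L]], paths$pipelineA)
  write_gff3(preds$pipelines[[2L]], paths$pipelineB)
  for (nm in c("hits", "domains", "tm", "taxonomy")) {
    obj <- switch(nm, hits = hits, domains = dom$domains, tm = dom$tm,
                  taxonomy = taxonomy)
    utils::write.table(obj, paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(truth = truth, predictions = preds, hits = hits,
                 domains = dom, taxonomy = taxonomy, paths = paths))
}
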