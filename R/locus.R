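# Locus integration: merge gene models from independent prediction sets
# into loci by single-linkage overlap clustering, sweep the overlap
# threshold, filter on homology evidence, select representative models and
# drop contaminant scaffolds.

#' Overlap fraction between two gene models
#'
#' Shared genomic-span length divided by the shorter genomic span. Models on
#' different scaffolds or strands have overlap 0. Spans are genomic extents
#' (introns included).
#'
#' @param a,b [gene_model()] objects.
#' @return Fraction in `[0, 1]`.
#' @examples
#' a <- gene_model("a", "x", "s1", "+", cbind(100, 400))
#' b <- gene_model("b", "x", "s1", "+", cbind(250, 550))
#' overlap_fraction(a, b)  # 150/300 = 0.5
#' @export
overlap_fraction <- function(a, b) {
  stopifnot(inherits(a, "gene_model"), inherits(b, "gene_model"))
  if (a$scaffold != b$scaffold || a$strand != b$strand) return(0)
  sa <- model_span(a); sb <- model_span(b)
  shared <- min(sa[2L], sb[2L]) - max(sa[1L], sb[1L])
  if (shared <= 0) return(0)
  shared / min(sa[2L] - sa[1L], sb[2L] - sb[1L])
}

# all overlapping pairs within one scaffold+strand block, vectorized sweep;
# returns two-column index matrix of pairs with overlap fraction >= threshold
overlap_pairs <- function(start, end, threshold) {
  n <- length(start)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  res <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    j <- j[s[j] < e[i]]
    if (length(j) == 0L) next
    shared <- pmin(e[i], e[j]) - pmax(s[i], s[j])
    frac <- shared / pmin(e[i] - s[i], e[j] - s[j])
    keep <- j[frac >= threshold & shared > 0]
    if (length(keep) > 0L) res[[i]] <- cbind(o[i], o[keep])
  }
  out <- do.call(rbind, res)
  if (is.null(out)) matrix(integer(0), ncol = 2L) else out
}

new_locus <- function(id, scaffold, strand, members) {
  structure(list(id = id, scaffold = scaffold, strand = strand,
                 members = members, representative = NULL, annotation = NULL),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus %s> %s(%s) %d member(s)%s\n", x$id, x$scaffold,
              x$strand, length(x$members),
              if (is.null(x$representative)) ""
              else paste0(", representative ", x$representative)))
  invisible(x)
}

#' Cluster gene models into loci by single-linkage overlap
#'
#' Models shorter than `min_orf_nt` of CDS are excluded first. The remaining
#' models are partitioned, per scaffold and strand, into connected components
#' of the graph that has an edge wherever [overlap_fraction()] is at least
#' `threshold` (single linkage: each member need only overlap one other
#' member). Locus ids are deterministic functions of (scaffold, strand,
#' leftmost span start).
#'
#' @param models List of [gene_model()]s.
#' @param threshold Overlap-fraction threshold in `(0, 1]`.
#' @param min_orf_nt Minimum CDS length (nt) retained; shorter predictions
#'   are discarded before clustering.
#' @return List of `locus` objects ordered by scaffold, start and strand.
#' @export
cluster_loci <- function(models, threshold, min_orf_nt = 300L) {
  stopifnot(threshold > 0, threshold <= 1)
  tab <- model_table(models)
  keep <- tab$cds_length >= min_orf_nt
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) return(list())
  loci <- list()
  for (key in split(seq_len(nrow(tab)),
                    paste(tab$scaffold, tab$strand, sep = "\r"))) {
    sub <- tab[key, , drop = FALSE]
    pairs <- overlap_pairs(sub$start, sub$end, threshold)
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = as.character(pairs[, 1L]),
                     to = as.character(pairs[, 2L])),
      directed = FALSE,
      vertices = data.frame(name = as.character(seq_len(nrow(sub))))
    )
    comp <- igraph::components(g)$membership
    for (members_i in split(seq_len(nrow(sub)), comp)) {
      ms <- sub$id[members_i][order(sub$start[members_i],
                                    sub$id[members_i])]
      left <- min(sub$start[members_i])
      id <- sprintf("LOC_%s_%s_%09d", sub$scaffold[1L],
                    if (sub$strand[1L] == "+") "p" else "m", left)
      loci[[id]] <- new_locus(id, sub$scaffold[1L], sub$strand[1L], ms)
    }
  }
  tabL <- data.frame(
    scaffold = vapply(loci, `[[`, "", "scaffold"),
    strand = vapply(loci, `[[`, "", "strand"),
    start = as.integer(sub("^.*_(\\d+)$", "\\1", names(loci)))
  )
  unname(loci[order(tabL$scaffold, tabL$start, tabL$strand)])
}

#' Sweep overlap thresholds and select the knee
#'
#' Runs [cluster_loci()] at each threshold and tabulates locus counts and the
#' single-model to multi-model locus ratio. The selected threshold is a
#' reproducible formalization of reading the "knee" off the sweep curve: the
#' threshold immediately before the largest forward jump of the single:multi
#' ratio (ties resolved toward the smaller threshold). The ratio is flagged
#' undefined (`NA`) where a threshold yields no multi-model locus, and such
#' differences are skipped. If no defined positive jump exists (e.g. the two
#' prediction sets are identical, so counts never change), the selection is
#' `NA`.
#'
#' @param models List of [gene_model()]s.
#' @param thresholds Increasing vector of at least 3 thresholds; default
#'   0.60 to 0.95 in 0.05 steps.
#' @param min_orf_nt Passed to [cluster_loci()].
#' @return List with `sweep` (`data.frame` of `threshold`, `n_loci`,
#'   `n_single_model_loci`, `n_multi_model_loci`, `single_to_multi_ratio`)
#'   and `selected_threshold` (numeric or `NA`).
#' @export
sweep_and_select <- function(models, thresholds = seq(0.60, 0.95, by = 0.05),
                             min_orf_nt = 300L) {
  stopifnot(length(thresholds) >= 3L, !is.unsorted(thresholds, strictly = TRUE),
            all(thresholds > 0), all(thresholds <= 1))
  rows <- lapply(thresholds, function(t) {
    loci <- cluster_loci(models, t, min_orf_nt)
    sizes <- lengths(lapply(loci, `[[`, "members"))
    n_single <- sum(sizes == 1L)
    n_multi <- sum(sizes > 1L)
    data.frame(threshold = t, n_loci = length(loci),
               n_single_model_loci = n_single,
               n_multi_model_loci = n_multi,
               single_to_multi_ratio = if (n_multi == 0L) NA_real_
                                       else n_single / n_multi)
  })
  sweep <- do.call(rbind, rows)
  r <- sweep$single_to_multi_ratio
  d <- r[-1L] - r[-length(r)]
  selected <- NA_real_
  if (any(!is.na(d)) && max(d, na.rm = TRUE) > 0) {
    i <- which(d == max(d, na.rm = TRUE))[1L]
    selected <- thresholds[i]
  }
  list(sweep = sweep, selected_threshold = selected)
}

#' Filter gene models on homology evidence
#'
#' Retains models with both protein and transcript support: at least one
#' `refseq_plant` hit with identity >= 50, bit score >= 100 and both
#' coverages >= 80, and at least one `mrna` hit with identity strictly
#' above 90. `mode = "union"` relaxes the conjunction to either class.
#'
#' @param models List of [gene_model()]s.
#' @param hits Hit `data.frame` ([read_homology_hits()] layout).
#' @param mode `"intersection"` (default) or `"union"`.
#' @return The retained subset of `models`.
#' @export
evidence_filter <- function(models, hits, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  refseq_ok <- unique(hits$query[
    hits$database == "refseq_plant" & hits$pct_identity >= 50 &
      hits$bit_score >= 100 & hits$query_cov >= 80 & hits$subject_cov >= 80])
  mrna_ok <- unique(hits$query[
    hits$database == "mrna" & hits$pct_identity > 90])
  ids <- vapply(models, `[[`, "", "id")
  keep <- if (mode == "intersection") ids %in% refseq_ok & ids %in% mrna_ok
          else ids %in% refseq_ok | ids %in% mrna_ok
  models[keep]
}

REPRESENTATIVE_BLACKLIST <- c("predicted", "putative", "hypothetical",
                              "unnamed", "uncharacterized")

#' Select the representative model of a locus
#'
#' Considers only `refseq_plant` hits of the locus members, excluding hits
#' with E-value above `e_max` and hits whose description contains a
#' blacklist word (`predicted`, `putative`, `hypothetical`, `unnamed`,
#' `uncharacterized`; case-insensitive substring). The representative is the
#' member whose best surviving hit has the lowest E-value; ties break by
#' higher bit score, then lexicographic model id. A locus with no surviving
#' hit is discarded (`NULL`).
#'
#' @param locus A `locus` from [cluster_loci()].
#' @param hits Hit `data.frame`.
#' @param e_max Maximum E-value retained (default `1e-10`).
#' @return The locus with `representative` and `annotation` set, or `NULL`.
#' @export
select_representative <- function(locus, hits, e_max = 1e-10) {
  stopifnot(inherits(locus, "locus"))
  h <- hits[hits$database == "refseq_plant" &
              hits$query %in% locus$members &
              hits$e_value <= e_max, , drop = FALSE]
  if (nrow(h) > 0L) {
    desc <- tolower(h$description)
    banned <- Reduce(`|`, lapply(REPRESENTATIVE_BLACKLIST, grepl, x = desc,
                                 fixed = TRUE))
    h <- h[!banned, , drop = FALSE]
  }
  if (nrow(h) == 0L) return(NULL)
  h <- h[order(h$e_value, -h$bit_score, h$query), , drop = FALSE]
  best <- h[1L, ]
  locus$representative <- best$query
  locus$annotation <- list(subject = best$subject,
                           description = best$description,
                           e_value = best$e_value)
  locus
}

#' @rdname select_representative
#' @param loci List of loci.
#' @export
select_representatives <- function(loci, hits, e_max = 1e-10) {
  out <- lapply(loci, select_representative, hits = hits, e_max = e_max)
  out[!vapply(out, is.null, NA)]
}

#' Remove loci on contaminant scaffolds
#'
#' A scaffold is a contaminant when its best whole-scaffold hit is bacterial
#' or plastid *and* it lacks support at all three levels (sister genome,
#' transcriptome, newer assembly). Scaffolds absent from the taxonomy table
#' are treated as plant nuclear.
#'
#' @param loci List of loci.
#' @param taxonomy `data.frame` from [read_scaffold_taxonomy()].
#' @return The retained loci.
#' @export
filter_contaminant_scaffolds <- function(loci, taxonomy) {
  bad <- taxonomy$scaffold[
    taxonomy$best_hit %in% c("bacterial", "plastid") &
      !taxonomy$support_sister & !taxonomy$support_transcriptome &
      !taxonomy$support_newer]
  loci[!vapply(loci, `[[`, "", "scaffold") %in% bad]
}

#' Run the full locus-integration workflow
#'
#' Pools the prediction sets, applies the homology-evidence filter, selects
#' the overlap threshold by sweep (unless given), clusters into loci, picks
#' representative models and removes contaminant scaffolds.
#'
#' @param prediction_sets List of gene-model lists (one per pipeline).
#' @param hits Hit `data.frame`.
#' @param taxonomy Optional scaffold-taxonomy `data.frame`.
#' @param threshold `"auto"` for sweep selection, or a fixed fraction.
#' @param min_orf_nt Minimum CDS length (nt).
#' @param thresholds Sweep grid when `threshold = "auto"`.
#' @param evidence_mode Passed to [evidence_filter()].
#' @return List of class `locus_merge`: `loci` (with representatives),
#'   `sweep`, `threshold`, `models` (the evidence-filtered input models),
#'   `locus_of` (named map model id -> locus id).
#' @export
merge_predictions <- function(prediction_sets, hits, taxonomy = NULL,
                              threshold = "auto", min_orf_nt = 300L,
                              thresholds = seq(0.60, 0.95, by = 0.05),
                              evidence_mode = "intersection") {
  models <- do.call(c, prediction_sets)
  models <- evidence_filter(models, hits, mode = evidence_mode)
  sweep <- NULL
  if (identical(threshold, "auto")) {
    sw <- sweep_and_select(models, thresholds, min_orf_nt)
    sweep <- sw$sweep
    threshold <- sw$selected_threshold
    if (is.na(threshold)) {
      warning("threshold sweep found no knee; falling back to 0.85",
              call. = FALSE)
      threshold <- 0.85
    }
  }
  loci <- cluster_loci(models, threshold, min_orf_nt)
  loci <- select_representatives(loci, hits)
  if (!is.null(taxonomy)) loci <- filter_contaminant_scaffolds(loci, taxonomy)
  member_ids <- unlist(lapply(loci, `[[`, "members"), use.names = FALSE)
  locus_of <- rep(vapply(loci, `[[`, "", "id"),
                  vapply(loci, function(l) length(l$members), 0L))
  names(locus_of) <- member_ids
  structure(list(loci = loci, sweep = sweep, threshold = threshold,
                 models = models, locus_of = locus_of),
            class = "locus_merge")
}

#' @export
print.locus_merge <- function(x, ...) {
  cat(sprintf(paste0("<locus_merge> %d loci from %d models at overlap ",
                     "threshold %.2f\n"),
              length(x$loci), length(x$models), x$threshold))
  invisible(x)
}

#' Write merged loci to GFF3
#'
#' Writes the member models of every merged locus with `locus_id` and
#' `representative` attributes.
#'
#' @param merge A `locus_merge` from [merge_predictions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_merged_gff3 <- function(merge, path) {
  stopifnot(inherits(merge, "locus_merge"))
  ids <- names(merge$locus_of)
  models <- Filter(function(m) m$id %in% ids, merge$models)
  reps <- unlist(lapply(merge$loci, `[[`, "representative"), use.names = FALSE)
  write_gff3(models, path, locus_of = merge$locus_of, representatives = reps)
}
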