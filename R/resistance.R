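# Candidate resistance (R) gene classification by protein-domain rules,
# and physical clustering of CNL genes along chromosomes.

R_CLASS_LEVELS <- c("CNL", "TNL", "Kinase", "RLP", "RLK", "Mlo-like",
                    "unclassified")

#' Classify candidate R genes from domain architectures
#'
#' Applies the six-class domain rule table: a gene must carry *all* the
#' domains of a class to be assigned to it. Rules are evaluated in priority
#' order TNL > CNL > RLK > RLP > Mlo-like > Kinase, so the TIR domain
#' discriminates TNL from CNL and the kinase domain discriminates RLK from
#' RLP:
#' * TNL: TIR + NBS + LRR
#' * CNL: CC + NBS + LRR
#' * RLK: TM + LRR + STK
#' * RLP: TM + LRR, without STK
#' * Mlo-like: MLO domain and 6 or 7 transmembrane helices
#' * Kinase: STK without TM/LRR/NBS
#' Anything else is `unclassified`. The classification is a pure function of
#' each gene's domain set and TM-helix count.
#'
#' @param domain_hits `data.frame` with columns `gene`, `domain`
#'   ([read_domain_hits()] layout).
#' @param tm_records `data.frame` with columns `gene`, `tm_helices`; genes
#'   absent from it count as 0 helices.
#' @return `data.frame` with one row per gene appearing in either input:
#'   `gene`, `domains` (comma-separated), `tm_helices`, `r_class`.
#' @export
classify_r_genes <- function(domain_hits, tm_records = NULL) {
  stopifnot(all(c("gene", "domain") %in% names(domain_hits)))
  genes <- sort(unique(c(domain_hits$gene,
                         if (!is.null(tm_records)) tm_records$gene)))
  dom_of <- lapply(split(domain_hits$domain, domain_hits$gene), unique)
  tm_of <- integer(0)
  if (!is.null(tm_records))
    tm_of <- stats::setNames(as.integer(tm_records$tm_helices),
                             tm_records$gene)
  rows <- lapply(genes, function(g) {
    d <- dom_of[[g]]
    if (is.null(d)) d <- character(0)
    tm <- if (g %in% names(tm_of)) tm_of[[g]] else 0L
    cls <-
      if (all(c("TIR", "NBS", "LRR") %in% d)) "TNL"
      else if (all(c("CC", "NBS", "LRR") %in% d)) "CNL"
      else if (all(c("TM", "LRR", "STK") %in% d)) "RLK"
      else if (all(c("TM", "LRR") %in% d)) "RLP"
      else if ("MLO" %in% d && tm %in% 6:7) "Mlo-like"
      else if ("STK" %in% d && !any(c("TM", "LRR", "NBS") %in% d)) "Kinase"
      else "unclassified"
    data.frame(gene = g, domains = paste(sort(d), collapse = ","),
               tm_helices = tm, r_class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), domains = character(),
                      tm_helices = integer(), r_class = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Detect physical clusters of CNL genes
#'
#' A cluster is a maximal run of CNL genes along a chromosome in which every
#' adjacent CNL pair is less than `max_gap` nt apart and separated by at
#' most `max_intervening` genes that carry neither an NBS nor an LRR domain
#' (genes with either domain do not count against the budget). Distance is
#' measured gene start to gene start by default. Runs of one gene are not
#' clusters.
#'
#' @param records Classification `data.frame` from [classify_r_genes()].
#' @param gene_positions `data.frame` with columns `gene`, `chromosome`,
#'   `start`, `end` for *all* positioned genes (needed to count intervening
#'   genes).
#' @param max_gap Maximum adjacent-pair distance in nt (strict `<`).
#' @param max_intervening Maximum intervening non-NBS-LRR genes per adjacent
#'   pair (inclusive `<=`).
#' @param measure `"start"` (start-to-start) or `"end_to_start"`.
#' @return `data.frame` with one row per cluster: `cluster_id`,
#'   `chromosome`, `n_members`, `start`, `end`, `members`
#'   (comma-separated gene ids).
#' @export
find_cnl_clusters <- function(records, gene_positions, max_gap = 200000L,
                              max_intervening = 8L,
                              measure = c("start", "end_to_start")) {
  measure <- match.arg(measure)
  stopifnot(all(c("gene", "r_class") %in% names(records)),
            all(c("gene", "chromosome", "start", "end") %in%
                  names(gene_positions)))
  pos <- gene_positions[order(gene_positions$chromosome,
                              gene_positions$start,
                              gene_positions$gene), , drop = FALSE]
  cnl <- records$gene[records$r_class == "CNL"]
  has_nbs_lrr <- records$gene[grepl("NBS|LRR", records$domains)]
  pos$is_cnl <- pos$gene %in% cnl
  pos$counts_against <- !pos$gene %in% has_nbs_lrr
  clusters <- list()
  for (chr in unique(pos$chromosome)) {
    p <- pos[pos$chromosome == chr, , drop = FALSE]
    ci <- which(p$is_cnl)
    if (length(ci) < 2L) next
    run <- ci[1L]
    flush <- function(run) {
      if (length(run) >= 2L)
        clusters[[length(clusters) + 1L]] <<- data.frame(
          chromosome = chr, n_members = length(run),
          start = min(p$start[run]), end = max(p$end[run]),
          members = paste(p$gene[run], collapse = ","),
          stringsAsFactors = FALSE)
    }
    for (k in seq_len(length(ci) - 1L)) {
      i <- ci[k]; j <- ci[k + 1L]
      dist <- if (measure == "start") p$start[j] - p$start[i]
              else p$start[j] - p$end[i]
      between <- if (j - i > 1L) (i + 1L):(j - 1L) else integer(0)
      n_interv <- sum(p$counts_against[between])
      if (dist < max_gap && n_interv <= max_intervening) {
        run <- c(run, j)
      } else {
        flush(run)
        run <- j
      }
    }
    flush(run)
  }
  out <- do.call(rbind, clusters)
  if (is.null(out))
    return(data.frame(cluster_id = character(), chromosome = character(),
                      n_members = integer(), start = integer(),
                      end = integer(), members = character(),
                      stringsAsFactors = FALSE))
  out$cluster_id <- sprintf("CNL_cluster_%03d", seq_len(nrow(out)))
  out[, c("cluster_id", "chromosome", "n_members", "start", "end", "members")]
}

#' Summarize R-gene classes
#'
#' @param records Classification `data.frame` from [classify_r_genes()].
#' @param gene_positions Optional positions (as in [find_cnl_clusters()])
#'   for a per-chromosome breakdown.
#' @param clusters Optional cluster table from [find_cnl_clusters()] to
#'   report the clustered-CNL fraction.
#' @return List with `class_counts` (named integer vector over all six
#'   classes plus `unclassified`), `class_fractions`, optionally
#'   `per_chromosome` (class x chromosome table) and `clustered_cnl`
#'   (count + fraction of CNL genes inside clusters).
#' @export
summarize_classes <- function(records, gene_positions = NULL,
                              clusters = NULL) {
  counts <- table(factor(records$r_class, levels = R_CLASS_LEVELS))
  out <- list(
    class_counts = stats::setNames(as.integer(counts), names(counts)),
    class_fractions = if (nrow(records) > 0L)
      as.vector(counts) / nrow(records) else rep(0, length(counts))
  )
  names(out$class_fractions) <- names(counts)
  if (!is.null(gene_positions)) {
    m <- merge(records, gene_positions, by = "gene")
    out$per_chromosome <- table(m$r_class, m$chromosome)
  }
  if (!is.null(clusters)) {
    in_clusters <- unlist(strsplit(clusters$members, ",", fixed = TRUE))
    n_cnl <- sum(records$r_class == "CNL")
    out$clustered_cnl <- list(
      n = length(unique(in_clusters)),
      fraction = if (n_cnl > 0L) length(unique(in_clusters)) / n_cnl
                 else NA_real_)
  }
  out
}
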