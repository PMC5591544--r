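# Independent oracles and random-instance generators used across tests.

# brute-force single-linkage oracle: all-pairs overlap matrix + union-find,
# written independently of cluster_loci (which goes through igraph)
oracle_partition <- function(models, threshold, min_orf_nt = 300L) {
  keep <- vapply(models, cds_length, 0L) >= min_orf_nt
  models <- models[keep]
  n <- length(models)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && overlap_fraction(models[[i]], models[[j]]) >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  ids <- vapply(models, `[[`, "", "id")
  unname(lapply(split(ids, roots), sort))
}

# canonical partition (sorted list of sorted member sets) for comparison
canonical_partition <- function(member_sets) {
  sets <- lapply(member_sets, sort)
  sets[order(vapply(sets, `[[`, "", 1L))]
}

# random gene-model instance on one or more scaffolds/strands
random_models <- function(n, n_scaffolds = 2L, span_max = 5000L,
                          len_range = c(300L, 1500L)) {
  lapply(seq_len(n), function(i) {
    len <- sample(len_range[1L]:len_range[2L], 1L)
    start <- sample.int(span_max, 1L)
    gene_model(sprintf("g%03d", i), sample(c("A", "B"), 1L),
               sprintf("s%d", sample.int(n_scaffolds, 1L)),
               sample(c("+", "-"), 1L), cbind(start, start + len))
  })
}

# chi-squared upper-tail probability by direct numerical integration of the
# density, independent of stats::pchisq
chisq_upper_oracle <- function(x, df) {
  dens <- function(t) t^(df / 2 - 1) * exp(-t / 2) / (2^(df / 2) * gamma(df / 2))
  if (x <= 0) return(1)
  stats::integrate(dens, lower = x, upper = Inf, rel.tol = 1e-12,
                   abs.tol = 0)$value
}

# random chromosome layout of positioned genes
make_layout <- function(n_genes, chromosome = "chr1", spacing_max = 100000L) {
  starts <- cumsum(sample.int(spacing_max, n_genes, replace = TRUE))
  data.frame(gene = sprintf("%s_g%03d", chromosome, seq_len(n_genes)),
             chromosome = chromosome,
             start = starts, end = starts + 2000L,
             stringsAsFactors = FALSE)
}

# records for a layout with given CNL positions and NBS/LRR carriers
layout_records <- function(pos, cnl_idx, nbslrr_idx = integer(0)) {
  doms <- rep("OTHER", nrow(pos))
  doms[nbslrr_idx] <- "NBS"
  doms[cnl_idx] <- "CC,LRR,NBS"
  data.frame(gene = pos$gene, domains = doms,
             tm_helices = 0L,
             r_class = ifelse(seq_len(nrow(pos)) %in% cnl_idx, "CNL",
                              "unclassified"),
             stringsAsFactors = FALSE)
}

# brute-force CNL cluster oracle: test all pairs, then transitive chaining
# over adjacent qualifying pairs
oracle_cnl_clusters <- function(records, gene_positions, max_gap = 200000L,
                                max_intervening = 8L) {
  pos <- gene_positions[order(gene_positions$chromosome,
                              gene_positions$start,
                              gene_positions$gene), , drop = FALSE]
  cls <- setNames(records$r_class, records$gene)
  doms <- setNames(records$domains, records$gene)
  out <- list()
  for (chr in unique(pos$chromosome)) {
    p <- pos[pos$chromosome == chr, , drop = FALSE]
    is_cnl <- !is.na(cls[p$gene]) & cls[p$gene] == "CNL"
    ci <- which(is_cnl)
    if (length(ci) < 2L) next
    # adjacency between consecutive CNL genes
    ok <- logical(max(length(ci) - 1L, 0L))
    for (k in seq_along(ok)) {
      i <- ci[k]; j <- ci[k + 1L]
      between <- if (j - i > 1L) p$gene[(i + 1L):(j - 1L)] else character(0)
      d <- doms[between]
      n_non <- sum(is.na(d) | !grepl("NBS|LRR", d))
      ok[k] <- (p$start[j] - p$start[i]) < max_gap && n_non <= max_intervening
    }
    # transitive chaining
    run <- p$gene[ci[1L]]
    for (k in seq_along(ok)) {
      if (ok[k]) run <- c(run, p$gene[ci[k + 1L]])
      else {
        if (length(run) >= 2L) out[[length(out) + 1L]] <- run
        run <- p$gene[ci[k + 1L]]
      }
    }
    if (length(run) >= 2L) out[[length(out) + 1L]] <- run
  }
  out
}
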