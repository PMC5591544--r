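# Coding-region nucleotide composition: GC3 = (C3+G3)/(L/3), CG3-skew =
# (C3-G3)/(C3+G3), CpG genomic signature rho_CG = f_CG/(f_C f_G), decile
# classes, positional gradients along the ORF, and three nucleotide models
# of coding sequence. Codons containing N and trailing partial codons are
# excluded from all counts.

BASES <- c("A", "C", "G", "T")

#' Third-codon-position composition of a CDS
#'
#' Splits the coding sequence into codons and counts C and G at third codon
#' positions. GC3 is `(C3 + G3) / n_codons` over valid codons (codons with an
#' N, and any trailing partial codon, are excluded); CG3-skew is
#' `(C3 - G3) / (C3 + G3)`, undefined (`NA`) when `C3 + G3 = 0`. GC is
#' computed over all bases of the valid codons.
#'
#' @param cds Coding sequence (5'->3'), upper-case ACGTN.
#' @param gene Gene id carried through to the profile.
#' @return Object of class `composition_profile` with fields `gene`, `L`
#'   (input length), `n_codons` (valid codons), `C3`, `G3`, `gc`, `gc3`,
#'   `cg3_skew` and `third_bases` (per-codon third base, `NA` where the
#'   codon was excluded).
#' @examples
#' codon_composition("ATGGCC")$gc3   # 1
#' codon_composition("ATGAAA")$gc3   # 0.5
#' @export
codon_composition <- function(cds, gene = NA_character_) {
  L <- nchar(cds)
  if (L < 3L) stop("CDS shorter than one codon: '", gene, "'")
  n_full <- L %/% 3L
  chars <- strsplit(substr(cds, 1L, n_full * 3L), "", fixed = TRUE)[[1L]]
  codon_mat <- matrix(chars, nrow = 3L)
  valid <- colSums(codon_mat == "N") == 0L
  third <- codon_mat[3L, ]
  third[!valid] <- NA_character_
  C3 <- sum(third == "C", na.rm = TRUE)
  G3 <- sum(third == "G", na.rm = TRUE)
  n_codons <- sum(valid)
  counted <- codon_mat[, valid, drop = FALSE]
  structure(list(
    gene = gene, L = L, n_codons = n_codons, C3 = C3, G3 = G3,
    gc = if (n_codons > 0L) mean(counted %in% c("G", "C")) else NA_real_,
    gc3 = if (n_codons > 0L) (C3 + G3) / n_codons else NA_real_,
    cg3_skew = if (C3 + G3 > 0L) (C3 - G3) / (C3 + G3) else NA_real_,
    third_bases = third
  ), class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf(paste0("<composition_profile %s> %d nt, %d codons, GC %.3f, ",
                     "GC3 %.3f, CG3-skew %s\n"),
              x$gene, x$L, x$n_codons, x$gc, x$gc3,
              if (is.na(x$cg3_skew)) "undefined" else sprintf("%.3f",
                                                             x$cg3_skew)))
  invisible(x)
}

#' Composition profiles for a set of gene models
#'
#' Extracts each model's spliced CDS and computes its
#' [codon_composition()].
#'
#' @param genome Named character vector from [read_fasta()].
#' @param models List of [gene_model()]s.
#' @return Named list of `composition_profile`s.
#' @export
composition_profiles <- function(genome, models) {
  profs <- lapply(models, function(m)
    codon_composition(extract_cds(genome, m), gene = m$id))
  names(profs) <- vapply(models, `[[`, "", "id")
  profs
}

#' Flatten composition profiles to a data frame
#'
#' @param profiles List of `composition_profile`s.
#' @return `data.frame` with one row per gene.
#' @export
profile_table <- function(profiles) {
  data.frame(
    gene = vapply(profiles, `[[`, "", "gene"),
    L = vapply(profiles, `[[`, 0L, "L"),
    n_codons = vapply(profiles, `[[`, 0L, "n_codons"),
    C3 = vapply(profiles, function(p) as.integer(p$C3), 0L),
    G3 = vapply(profiles, function(p) as.integer(p$G3), 0L),
    gc = vapply(profiles, `[[`, 0, "gc"),
    gc3 = vapply(profiles, `[[`, 0, "gc3"),
    cg3_skew = vapply(profiles, `[[`, 0, "cg3_skew"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' CpG genomic signature of a sequence
#'
#' The dinucleotide relative abundance `rho_CG = f_CG / (f_C * f_G)`, with
#' `f_CG` over all overlapping dinucleotide positions and mononucleotide
#' frequencies over all bases. `rho_CG` is undefined (`NA`) when
#' `f_C * f_G = 0`.
#'
#' @param seq Upper-case sequence of length >= 2.
#' @return List with `rho_cg`, `f_cg`, `f_c`, `f_g`.
#' @examples
#' genomic_signature("CGCG")$rho_cg  # 8/3
#' @export
genomic_signature <- function(seq) {
  L <- nchar(seq)
  if (L < 2L) stop("sequence shorter than one dinucleotide")
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1L]]
  n_cg <- if (hits[1L] == -1L) 0L else length(hits)
  f_cg <- n_cg / (L - 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  f_c <- mean(chars == "C")
  f_g <- mean(chars == "G")
  list(rho_cg = if (f_c * f_g > 0) f_cg / (f_c * f_g) else NA_real_,
       f_cg = f_cg, f_c = f_c, f_g = f_g)
}

#' Split genes into GC3-rich and GC3-poor deciles
#'
#' Ranks genes by GC3 and takes the top and bottom `prop` (default 10%) as
#' the rich and poor classes. Class size is `round(prop * N)` with half-up
#' rounding by default; boundary ties are broken by gene id so the sizes are
#' exact. Thresholds report the minimum GC3 of the rich class and the
#' maximum GC3 of the poor class.
#'
#' @param profiles List of `composition_profile`s or a [profile_table()]
#'   `data.frame` with columns `gene`, `gc3`.
#' @param prop Fraction per class.
#' @param rounding `"half-up"`, `"floor"` or `"ceiling"`.
#' @return List with `rich`, `poor` (gene ids), `rich_threshold`,
#'   `poor_threshold` and `n_per_class`.
#' @export
classify_deciles <- function(profiles, prop = 0.1,
                             rounding = c("half-up", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  tab <- if (is.data.frame(profiles)) profiles else profile_table(profiles)
  stopifnot(all(c("gene", "gc3") %in% names(tab)))
  N <- nrow(tab)
  if (N < 10L) stop("need at least 10 genes to form deciles, got ", N)
  n <- switch(rounding,
              "half-up" = floor(prop * N + 0.5),
              "floor" = floor(prop * N),
              "ceiling" = ceiling(prop * N))
  rich_ord <- order(-tab$gc3, tab$gene)
  poor_ord <- order(tab$gc3, tab$gene)
  rich <- tab$gene[rich_ord[seq_len(n)]]
  poor <- tab$gene[poor_ord[seq_len(n)]]
  list(rich = rich, poor = poor,
       rich_threshold = min(tab$gc3[rich_ord[seq_len(n)]]),
       poor_threshold = max(tab$gc3[poor_ord[seq_len(n)]]),
       n_per_class = n)
}

#' Positional gradients of GC3 and CG3-skew along the ORF
#'
#' At codon index k, averages over the genes that are at least k codons
#' long: for GC3 the indicator that the third base is G or C; for CG3-skew
#' the signed indicator (+1 for C, -1 for G; codons with A/T third base are
#' excluded from the skew mean). No padding or smoothing is applied;
#' `n_genes` records how many genes contribute at each index.
#'
#' @param profiles List of `composition_profile`s.
#' @param max_codon Truncate curves at this codon index (default: longest
#'   gene).
#' @return List of two `data.frame`s, `gc3` and `cg3_skew`, each with
#'   columns `codon_index`, `mean_value`, `n_genes`.
#' @export
positional_gradients <- function(profiles, max_codon = NULL) {
  stopifnot(length(profiles) > 0L)
  thirds <- lapply(profiles, `[[`, "third_bases")
  K <- max(lengths(thirds))
  if (!is.null(max_codon)) K <- min(K, max_codon)
  n_genes <- integer(K); n_obs <- integer(K)
  gc_count <- integer(K); c_count <- integer(K); g_count <- integer(K)
  for (tb in thirds) {
    k <- min(length(tb), K)
    if (k == 0L) next
    idx <- seq_len(k)
    n_genes[idx] <- n_genes[idx] + 1L
    tbk <- tb[idx]
    ok <- !is.na(tbk)
    n_obs[idx] <- n_obs[idx] + ok
    gc_count[idx] <- gc_count[idx] + (ok & tbk %in% c("G", "C"))
    c_count[idx] <- c_count[idx] + (ok & tbk == "C")
    g_count[idx] <- g_count[idx] + (ok & tbk == "G")
  }
  gc3 <- data.frame(codon_index = seq_len(K),
                    mean_value = ifelse(n_obs > 0L, gc_count / n_obs, NA_real_),
                    n_genes = n_genes)
  cg <- c_count + g_count
  skew <- data.frame(codon_index = seq_len(K),
                     mean_value = ifelse(cg > 0L,
                                         (c_count - g_count) / cg, NA_real_),
                     n_genes = n_genes)
  list(gc3 = gc3, cg3_skew = skew)
}

#' Fit a nucleotide model of coding sequence
#'
#' Maximum-likelihood fit of one of three models to a set of coding
#' sequences, using only complete codons free of N:
#' * `multinomial` - one base-frequency vector, codon position ignored;
#' * `position_specific` - one base-frequency vector per codon position
#'   (3 x 4);
#' * `markov3` - first-order, codon-position-periodic Markov chain: each
#'   base conditioned on the preceding base, with a separate 4 x 4
#'   transition matrix per codon position of the *current* base. The first
#'   base of each sequence has no predecessor and is skipped.
#'
#' @param cds_set Character vector of coding sequences.
#' @param kind Model kind.
#' @param smoothing Add-`smoothing` pseudo-count (default 0, off).
#' @return Object of class `nucleotide_model`: `kind`, `probs` (vector,
#'   matrix, or list of 3 matrices indexed by codon position), and
#'   `training_codons`.
#' @export
fit_nucleotide_models <- function(cds_set,
                                  kind = c("multinomial", "position_specific",
                                           "markov3"),
                                  smoothing = 0) {
  kind <- match.arg(kind)
  stopifnot(length(cds_set) > 0L, smoothing >= 0)
  mats <- lapply(cds_set, function(cds) {
    n_full <- nchar(cds) %/% 3L
    if (n_full == 0L) return(NULL)
    m <- matrix(strsplit(substr(cds, 1L, n_full * 3L), "")[[1L]], nrow = 3L)
    m[, colSums(m == "N") == 0L, drop = FALSE]
  })
  mats <- mats[!vapply(mats, is.null, NA)]
  total_codons <- sum(vapply(mats, ncol, 0L))
  if (total_codons == 0L) stop("no complete N-free codon in cds_set")
  probs <- switch(kind,
    multinomial = {
      # codon position is irrelevant here, so every non-N base counts,
      # including bases of a trailing partial codon
      chars <- unlist(strsplit(cds_set, "", fixed = TRUE))
      counts <- table(factor(chars[chars != "N"], levels = BASES)) + smoothing
      p <- as.vector(counts / sum(counts))
      names(p) <- BASES
      p
    },
    position_specific = {
      counts <- t(vapply(1:3, function(pos) {
        table(factor(unlist(lapply(mats, function(m) m[pos, ])),
                     levels = BASES)) + smoothing
      }, numeric(4L)))
      dimnames(counts) <- list(position = 1:3, base = BASES)
      counts / rowSums(counts)
    },
    markov3 = {
      counts <- lapply(1:3, function(i)
        matrix(smoothing, 4L, 4L, dimnames = list(prev = BASES, cur = BASES)))
      for (m in mats) {
        v <- as.vector(m)
        if (length(v) < 2L) next
        prev <- v[-length(v)]
        cur <- v[-1L]
        pos <- ((seq_along(v)[-1L] - 1L) %% 3L) + 1L  # position of current base
        for (p in 1:3) {
          sel <- pos == p
          if (!any(sel)) next
          counts[[p]] <- counts[[p]] +
            table(factor(prev[sel], levels = BASES),
                  factor(cur[sel], levels = BASES))
        }
      }
      lapply(counts, function(cm) {
        rs <- rowSums(cm)
        out <- cm / ifelse(rs > 0, rs, NA_real_)
        out
      })
    })
  structure(list(kind = kind, probs = probs, training_codons = total_codons),
            class = "nucleotide_model")
}

#' @export
print.nucleotide_model <- function(x, ...) {
  cat(sprintf("<nucleotide_model %s> trained on %d codons\n", x$kind,
              x$training_codons))
  invisible(x)
}

#' Log-likelihood of coding sequences under a nucleotide model
#'
#' Scores complete, N-free codons; for `markov3` the first base of each
#' sequence is skipped (it has no predecessor), mirroring the fit.
#'
#' @param model A `nucleotide_model`.
#' @param cds_set Character vector of coding sequences.
#' @return Total log-likelihood (natural log).
#' @export
loglik_nucleotide_model <- function(model, cds_set) {
  stopifnot(inherits(model, "nucleotide_model"))
  ll <- 0
  for (cds in cds_set) {
    n_full <- nchar(cds) %/% 3L
    if (n_full == 0L) next
    m <- matrix(strsplit(substr(cds, 1L, n_full * 3L), "")[[1L]], nrow = 3L)
    m <- m[, colSums(m == "N") == 0L, drop = FALSE]
    v <- as.vector(m)
    if (length(v) == 0L) next
    ll <- ll + switch(model$kind,
      multinomial = sum(log(model$probs[v])),
      position_specific = {
        pos <- ((seq_along(v) - 1L) %% 3L) + 1L
        sum(log(model$probs[cbind(pos, match(v, BASES))]))
      },
      markov3 = {
        if (length(v) < 2L) 0 else {
          prev <- match(v[-length(v)], BASES)
          cur <- match(v[-1L], BASES)
          pos <- ((seq_along(v)[-1L] - 1L) %% 3L) + 1L
          sum(vapply(seq_along(cur), function(i)
            log(model$probs[[pos[i]]][prev[i], cur[i]]), 0))
        }
      })
  }
  ll
}

#' Sample coding sequence from a codon-position-periodic Markov model
#'
#' Generates a sequence of `n_codons` codons from first-order transition
#' matrices indexed by the codon position of the current base, starting from
#' a uniformly drawn first base. Useful for parameter-recovery checks.
#'
#' @param trans List of 3 row-stochastic 4 x 4 matrices (`prev` x `cur`,
#'   bases A,C,G,T) indexed by codon position of the current base.
#' @param n_codons Number of codons to generate.
#' @return Character scalar of length `3 * n_codons`.
#' @export
sample_markov3_cds <- function(trans, n_codons) {
  stopifnot(length(trans) == 3L,
            all(vapply(trans, function(m) all(dim(m) == c(4L, 4L)), NA)))
  n <- 3L * n_codons
  idx <- integer(n)
  idx[1L] <- sample.int(4L, 1L)
  for (i in 2:n) {
    p <- ((i - 1L) %% 3L) + 1L
    idx[i] <- sample.int(4L, 1L, prob = trans[[p]][idx[i - 1L], ])
  }
  paste(BASES[idx], collapse = "")
}

#' Per-category goodness-of-fit test of rich/poor gene counts
#'
#' For each functional category, compares the observed split of genes
#' between the GC3-rich and GC3-poor classes against the split expected if
#' category membership were independent of composition class. Expected
#' counts are proportional to the background weights (default equal, as for
#' equal-sized deciles): `E = total * w / sum(w)` per cell. Each category is
#' tested with a chi-squared statistic on its 2 cells (df = 1).
#'
#' @param observed_rich,observed_poor Integer vectors of per-category gene
#'   counts in the rich and poor classes (equal length, aligned; names from
#'   `observed_rich` are carried through).
#' @param background_rich,background_poor Optional per-category expected
#'   weights; default equal weights.
#' @return `data.frame` with per-category observed/expected counts,
#'   `chi_squared`, `df` and `p_value` (upper tail).
#' @examples
#' enrichment_test(10, 30)  # chi-squared 10, p ~ 1.57e-3
#' @export
enrichment_test <- function(observed_rich, observed_poor,
                            background_rich = NULL, background_poor = NULL) {
  stopifnot(length(observed_rich) == length(observed_poor),
            all(observed_rich >= 0), all(observed_poor >= 0))
  k <- length(observed_rich)
  if (is.null(background_rich)) background_rich <- rep(1, k)
  if (is.null(background_poor)) background_poor <- rep(1, k)
  stopifnot(length(background_rich) == k, length(background_poor) == k)
  categories <- if (!is.null(names(observed_rich))) names(observed_rich)
                else paste0("category_", seq_len(k))
  total <- observed_rich + observed_poor
  w <- background_rich + background_poor
  e_rich <- total * background_rich / w
  e_poor <- total * background_poor / w
  if (any(e_rich == 0 | e_poor == 0))
    stop("expected count of 0 in category '",
         categories[which(e_rich == 0 | e_poor == 0)[1L]], "'")
  chi2 <- (observed_rich - e_rich)^2 / e_rich +
    (observed_poor - e_poor)^2 / e_poor
  data.frame(category = categories,
             observed_rich = observed_rich, observed_poor = observed_poor,
             expected_rich = e_rich, expected_poor = e_poor,
             chi_squared = chi2, df = 1L,
             p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}
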