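# Gene-structure statistics, intronless-gene (IG) identification, and
# homology-based taxonomic-sharing classification of IG.

#' Exon/CDS summary statistics
#'
#' @param models List of [gene_model()]s.
#' @return List of class `structure_summary`: `exon_count_histogram` (named
#'   integer vector), `mean_exons`, `mean_cds_length` (nt),
#'   `fraction_intronless` (fraction of mono-exonic models, before any ORF
#'   check), `n_models`.
#' @export
exon_stats <- function(models) {
  if (length(models) == 0L) stop("no models")
  tab <- model_table(models)
  hist <- table(tab$n_exons)
  structure(list(
    exon_count_histogram = stats::setNames(as.integer(hist), names(hist)),
    mean_exons = mean(tab$n_exons),
    mean_cds_length = mean(tab$cds_length),
    fraction_intronless = mean(tab$n_exons == 1L),
    n_models = nrow(tab)
  ), class = "structure_summary")
}

#' @export
print.structure_summary <- function(x, ...) {
  cat(sprintf(paste0("<structure_summary> %d models, mean %.2f exons, mean ",
                     "CDS %.0f nt, %.1f%% mono-exonic\n"),
              x$n_models, x$mean_exons, x$mean_cds_length,
              100 * x$fraction_intronless))
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# is the spliced CDS a complete ORF: ATG start, terminal stop, frame 0,
# no internal in-frame stop
is_full_orf <- function(cds) {
  L <- nchar(cds)
  if (L < 6L || L %% 3L != 0L) return(FALSE)
  if (substr(cds, 1L, 3L) != "ATG") return(FALSE)
  codons <- substring(cds, seq(1L, L - 2L, by = 3L), seq(3L, L, by = 3L))
  n <- length(codons)
  codons[n] %in% STOP_CODONS && !any(codons[-n] %in% STOP_CODONS)
}

#' Identify intronless genes
#'
#' An intronless gene (IG) is a mono-exonic model whose CDS is a complete
#' ORF: it starts with ATG, ends with a stop codon (TAA/TAG/TGA), has length
#' divisible by 3 and contains no internal in-frame stop.
#'
#' @param models List of [gene_model()]s.
#' @param genome Named character vector from [read_fasta()].
#' @return Character vector of IG model ids.
#' @export
find_intronless <- function(models, genome) {
  mono <- Filter(function(m) exon_count(m) == 1L, models)
  ids <- vapply(mono, `[[`, "", "id")
  ok <- vapply(mono, function(m) is_full_orf(extract_cds(genome, m)), NA)
  ids[ok]
}

KINGDOM_TAGS <- c("archaea", "bacteria", "eukaryote")
EUK_GROUP_TAGS <- c("viridiplantae", "fungi", "metazoa")

#' Classify intronless genes by taxonomic sharing
#'
#' A kingdom (archaea, bacteria, eukaryote) or eukaryote group
#' (viridiplantae, fungi, metazoa) is "hit" when the gene has at least one
#' homology hit in that database at `e_value <= e_cutoff`; a hit in a
#' eukaryote group implies the eukaryote kingdom. Genes are then
#' partitioned: `all-three-domains`, `eukaryote-bacteria`,
#' `eukaryote-archaea`, `archaea-bacteria`, `bacteria-only`,
#' `archaea-only`, `viridiplantae-only` (eukaryote hits restricted to green
#' plants), `eukaryote-other` (eukaryote-level hits with no named group),
#' `eukaryote-only` (two or more groups, no other kingdom), or `ORFan` (no
#' hit anywhere at the cutoff).
#'
#' @param ig_ids Character vector of gene ids.
#' @param hits Hit `data.frame` ([read_homology_hits()] layout).
#' @param e_cutoff E-value cutoff (inclusive), default `1e-5`.
#' @return `data.frame` with columns `gene`, `category`, `kingdoms`,
#'   `groups` (comma-separated tag lists, empty string when none).
#' @export
classify_kingdom_sharing <- function(ig_ids, hits, e_cutoff = 1e-5) {
  h <- hits[hits$query %in% ig_ids & hits$e_value <= e_cutoff, , drop = FALSE]
  res <- lapply(ig_ids, function(id) {
    db <- unique(h$database[h$query == id])
    groups <- intersect(db, EUK_GROUP_TAGS)
    kingdoms <- intersect(db, KINGDOM_TAGS)
    if (length(groups) > 0L) kingdoms <- union(kingdoms, "eukaryote")
    kingdoms <- intersect(KINGDOM_TAGS, kingdoms)  # canonical order
    has <- KINGDOM_TAGS %in% kingdoms
    category <-
      if (!any(has)) "ORFan"
      else if (all(has)) "all-three-domains"
      else if (has[3L] && has[2L]) "eukaryote-bacteria"
      else if (has[3L] && has[1L]) "eukaryote-archaea"
      else if (has[1L] && has[2L]) "archaea-bacteria"
      else if (has[2L]) "bacteria-only"
      else if (has[1L]) "archaea-only"
      else if (identical(groups, "viridiplantae")) "viridiplantae-only"
      else if (length(groups) == 0L) "eukaryote-other"
      else "eukaryote-only"
    data.frame(gene = id, category = category,
               kingdoms = paste(kingdoms, collapse = ","),
               groups = paste(intersect(EUK_GROUP_TAGS, groups),
                              collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(gene = character(),
                                      category = character(),
                                      kingdoms = character(),
                                      groups = character(),
                                      stringsAsFactors = FALSE)
  out
}

#' Fraction of intronless genes with intronless orthologs
#'
#' Flags each IG that has at least one mono-exonic ortholog in the reference
#' species set. The fraction's denominator is either the IG that have at
#' least one ortholog (default) or all IG.
#'
#' @param ig_ids Character vector of IG ids.
#' @param orthologs `data.frame` with columns `gene`, `species`, `ortholog`,
#'   `exon_count` (one row per ortholog pair).
#' @param denominator `"with_orthologs"` (default) or `"all"`.
#' @return List with `fraction` (`NA` when the denominator is empty),
#'   `n_flagged`, `n_denominator` and `flags` (`data.frame` of `gene`,
#'   `has_ortholog`, `has_intronless_ortholog`).
#' @export
ortholog_intronless_fraction <- function(ig_ids, orthologs,
                                         denominator = c("with_orthologs",
                                                         "all")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("gene", "species", "ortholog", "exon_count") %in%
                  names(orthologs)))
  has_orth <- ig_ids %in% orthologs$gene
  mono_genes <- unique(orthologs$gene[orthologs$exon_count == 1L])
  flagged <- ig_ids %in% mono_genes
  denom <- if (denominator == "with_orthologs") sum(has_orth)
           else length(ig_ids)
  list(fraction = if (denom > 0L) sum(flagged) / denom else NA_real_,
       n_flagged = sum(flagged),
       n_denominator = denom,
       flags = data.frame(gene = ig_ids, has_ortholog = has_orth,
                          has_intronless_ortholog = flagged,
                          stringsAsFactors = FALSE))
}
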