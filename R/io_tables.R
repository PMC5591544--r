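# Tab-separated evidence tables: homology hits, protein domains,
# transmembrane-helix counts, per-scaffold taxonomy. Fixed headers; rows
# failing bounds validation are dropped with a warning naming their row.

DOMAIN_VOCAB <- c("CC", "TIR", "NBS", "LRR", "STK", "TM", "MLO", "OTHER")
HIT_DATABASES <- c("refseq_plant", "mrna", "archaea", "bacteria",
                   "eukaryote", "viridiplantae", "fungi", "metazoa")
TAXONOMY_TAGS <- c("plant_nuclear", "bacterial", "plastid", "none")

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(what, " table '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}

drop_bad_rows <- function(df, bad, what) {
  if (any(bad)) {
    warning(sum(bad), " ", what, " row(s) rejected by validation: row ",
            paste(which(bad), collapse = ", "), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read a homology-hit table
#'
#' Tab-separated with header columns `query`, `subject`, `description`,
#' `database`, `e_value`, `bit_score`, `pct_identity`, `query_cov`,
#' `subject_cov` (tabular protein-alignment output, one row per hit). Rows
#' with out-of-bounds identity/coverages, negative E-values or unknown
#' database tags are rejected with a warning.
#'
#' @param path Path to the table.
#' @return `data.frame` of validated hits.
#' @export
read_homology_hits <- function(path) {
  df <- read_tsv_checked(path, c("query", "subject", "description", "database",
                                 "e_value", "bit_score", "pct_identity",
                                 "query_cov", "subject_cov"), "homology-hit")
  if (nrow(df) == 0L) return(df)
  for (col in c("e_value", "bit_score", "pct_identity", "query_cov",
                "subject_cov")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (col == "e_value" && anyNA(v))
      stop("non-numeric e_value in homology-hit table at row ",
           which(is.na(v))[1L])
    df[[col]] <- v
  }
  bad <- is.na(df$bit_score) | is.na(df$pct_identity) | is.na(df$query_cov) |
    is.na(df$subject_cov) | df$e_value < 0 |
    df$pct_identity < 0 | df$pct_identity > 100 |
    df$query_cov < 0 | df$query_cov > 100 |
    df$subject_cov < 0 | df$subject_cov > 100 |
    !df$database %in% HIT_DATABASES
  drop_bad_rows(df, bad, "homology-hit")
}

#' Read a protein-domain table
#'
#' Tab-separated with header columns `gene`, `domain` (one row per detected
#' domain, summarized from a domain-scan run). Domain labels outside the
#' controlled vocabulary (CC, TIR, NBS, LRR, STK, TM, MLO, OTHER) are mapped
#' to `OTHER` with a warning.
#'
#' @param path Path to the table.
#' @return `data.frame` with columns `gene`, `domain`.
#' @export
read_domain_hits <- function(path) {
  df <- read_tsv_checked(path, c("gene", "domain"), "domain")
  if (nrow(df) == 0L) return(df[, c("gene", "domain")])
  unknown <- !df$domain %in% DOMAIN_VOCAB
  if (any(unknown)) {
    warning("unknown domain label(s) mapped to OTHER: ",
            paste(unique(df$domain[unknown]), collapse = ", "), call. = FALSE)
    df$domain[unknown] <- "OTHER"
  }
  df[, c("gene", "domain")]
}

#' Read a transmembrane-helix count table
#'
#' Tab-separated with header columns `gene`, `tm_helices` (predicted
#' transmembrane helices per protein). Negative or non-integer counts are
#' rejected with a warning.
#'
#' @param path Path to the table.
#' @return `data.frame` with columns `gene`, `tm_helices`.
#' @export
read_tm_records <- function(path) {
  df <- read_tsv_checked(path, c("gene", "tm_helices"), "TM-helix")
  if (nrow(df) == 0L) return(df[, c("gene", "tm_helices")])
  v <- suppressWarnings(as.numeric(df$tm_helices))
  bad <- is.na(v) | v < 0 | v != floor(v)
  df$tm_helices <- as.integer(v)
  drop_bad_rows(df[, c("gene", "tm_helices")], bad, "TM-helix")
}

#' Read a per-scaffold taxonomy table
#'
#' Tab-separated with header columns `scaffold`, `best_hit`,
#' `support_sister`, `support_transcriptome`, `support_newer`: the best
#' whole-scaffold alignment class (`plant_nuclear`, `bacterial`, `plastid`,
#' `none`) plus three logical support flags from a sister genome, the
#' transcriptome and a newer assembly.
#'
#' @param path Path to the table.
#' @return `data.frame` of validated records.
#' @export
read_scaffold_taxonomy <- function(path) {
  df <- read_tsv_checked(path, c("scaffold", "best_hit", "support_sister",
                                 "support_transcriptome", "support_newer"),
                         "taxonomy")
  if (nrow(df) == 0L) return(df)
  for (col in c("support_sister", "support_transcriptome", "support_newer"))
    df[[col]] <- as.logical(df[[col]])
  bad <- !df$best_hit %in% TAXONOMY_TAGS |
    is.na(df$support_sister) | is.na(df$support_transcriptome) |
    is.na(df$support_newer)
  drop_bad_rows(df, bad, "taxonomy")
}

#' Read all four evidence tables at once
#'
#' @param hits_path,domains_path,tm_path,taxonomy_path Paths to the
#'   homology-hit, domain, TM-helix and taxonomy tables.
#' @return List with elements `hits`, `domains`, `tm`, `taxonomy`.
#' @export
read_evidence_tables <- function(hits_path, domains_path, tm_path,
                                 taxonomy_path) {
  list(hits = read_homology_hits(hits_path),
       domains = read_domain_hits(domains_path),
       tm = read_tm_records(tm_path),
       taxonomy = read_scaffold_taxonomy(taxonomy_path))
}
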