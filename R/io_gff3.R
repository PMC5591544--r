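# GFF3 input/output. Files use the 1-based inclusive GFF3 convention;
# everything in memory is 0-based half-open. Reading goes through
# rtracklayer; writing is plain line output so the merged-locus attributes
# and record order are byte-deterministic.

#' Read gene models from a GFF3 file
#'
#' Builds one [gene_model()] per mRNA (identified by the `Parent` attribute of
#' its CDS rows). Coordinates are converted from 1-based inclusive to 0-based
#' half-open; segments are sorted by ascending start regardless of strand.
#'
#' @param path Path to a GFF3 file with gene/mRNA/CDS rows.
#' @param source_label Optional prediction-set label applied to all models;
#'   default `NULL` takes each model's label from the GFF3 source column.
#' @return List of `gene_model` objects, ordered by scaffold and start.
#' @export
read_gff3 <- function(path, source_label = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0L) return(list())
  type <- as.character(gr$type)
  cds <- gr[type == "CDS"]
  if (length(cds) == 0L) return(list())
  parents <- cds$Parent
  if (is.null(parents) || any(lengths(parents) == 0L))
    stop("CDS feature without a Parent attribute in '", path, "'",
         if (!is.null(parents))
           paste0(" (CDS feature ", which(lengths(parents) == 0L)[1L], ")"))
  if (any(lengths(parents) > 1L))
    stop("CDS features with multiple Parent values are not supported")
  parent <- unlist(parents, use.names = FALSE)
  src <- as.character(cds$source)
  strand <- as.character(BiocGenerics::strand(cds))
  if (any(!strand %in% c("+", "-")))
    stop("unknown strand symbol for CDS of '",
         parent[which(!strand %in% c("+", "-"))[1L]], "'")
  scaf <- as.character(GenomicRanges::seqnames(cds))
  start0 <- BiocGenerics::start(cds) - 1L  # to 0-based half-open
  end0 <- BiocGenerics::end(cds)
  models <- lapply(split(seq_along(cds), parent), function(i) {
    if (length(unique(scaf[i])) != 1L)
      stop("CDS of '", parent[i[1L]], "' span multiple scaffolds")
    if (length(unique(strand[i])) != 1L)
      stop("CDS of '", parent[i[1L]], "' mix strands")
    o <- order(start0[i])
    gene_model(
      id = parent[i[1L]],
      source = if (is.null(source_label)) src[i[1L]] else source_label,
      scaffold = scaf[i[1L]],
      strand = strand[i[1L]],
      segments = cbind(start0[i][o], end0[i][o])
    )
  })
  models <- unname(models)
  tab <- model_table(models)
  models[order(tab$scaffold, tab$start, tab$id)]
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

# CDS phases in translation order (ascending segments for +, descending for -)
cds_phases <- function(segments, strand) {
  lens <- segments[, 2L] - segments[, 1L]
  ord <- if (strand == "+") seq_along(lens) else rev(seq_along(lens))
  before <- cumsum(c(0L, lens[ord]))[seq_along(lens)]
  phase <- (3L - before %% 3L) %% 3L
  phase[order(ord)]
}

#' Write gene models to GFF3
#'
#' Emits one mRNA row plus its CDS rows per model, 1-based inclusive, sorted
#' by scaffold, span start and id. Output is byte-deterministic for identical
#' input, and `read_gff3(write_gff3(models))` reproduces the models exactly.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @param locus_of Optional named character vector mapping model id to locus
#'   id; written as a `locus_id` attribute.
#' @param representatives Optional character vector of model ids to flag with
#'   `representative=true`.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, locus_of = NULL, representatives = NULL) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(models) == 0L) return(invisible(path))
  tab <- model_table(models)
  for (i in order(tab$scaffold, tab$start, tab$id)) {
    m <- models[[i]]
    sp <- model_span(m)
    attrs <- sprintf("ID=%s", gff3_escape(m$id))
    if (!is.null(locus_of) && m$id %in% names(locus_of))
      attrs <- paste0(attrs, ";locus_id=", gff3_escape(locus_of[[m$id]]))
    if (!is.null(representatives))
      attrs <- paste0(attrs, ";representative=",
                      if (m$id %in% representatives) "true" else "false")
    writeLines(sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\t%s",
                       m$scaffold, m$source, sp[1L] + 1L, sp[2L],
                       m$strand, attrs), con)
    ph <- cds_phases(m$segments, m$strand)
    writeLines(sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s;Parent=%s",
                       m$scaffold, m$source,
                       m$segments[, 1L] + 1L, m$segments[, 2L],
                       m$strand, ph,
                       gff3_escape(paste0(m$id, ".cds", seq_len(nrow(m$segments)))),
                       gff3_escape(m$id)), con)
  }
  invisible(path)
}
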