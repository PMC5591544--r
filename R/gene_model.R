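# Gene models: the unit record shared by every stage of the pipeline.
#
# Coordinates are 0-based half-open on the forward strand throughout the
# package; conversion to/from the 1-based inclusive GFF3 convention happens
# only at file boundaries. Segments are stored in ascending forward-strand
# order for both strands; strand is applied only when sequence is extracted.

#' Construct a gene model
#'
#' A gene model is one predicted coding gene: an ordered set of CDS segments
#' on one scaffold and strand, labelled with the prediction pipeline it came
#' from. Segments use 0-based half-open forward-strand coordinates and must be
#' sorted, non-overlapping and non-empty.
#'
#' @param id Unique model identifier.
#' @param source Prediction-set label (e.g. `"pipelineA"`).
#' @param scaffold Scaffold/sequence identifier.
#' @param strand `"+"` or `"-"`.
#' @param segments Two-column numeric matrix of `start`, `end` pairs
#'   (0-based half-open), one row per CDS segment.
#' @return An object of class `gene_model`.
#' @examples
#' m <- gene_model("g1", "demo", "s1", "+", cbind(c(0, 20), c(9, 30)))
#' cds_length(m)   # 19
#' exon_count(m)   # 2
#' @export
gene_model <- function(id, source, scaffold, strand, segments) {
  if (!is.matrix(segments)) segments <- matrix(segments, ncol = 2)
  storage.mode(segments) <- "integer"
  colnames(segments) <- c("start", "end")
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(scaffold), length(scaffold) == 1L)
  if (!strand %in% c("+", "-"))
    stop("gene model '", id, "': strand must be '+' or '-', got '", strand, "'")
  if (nrow(segments) < 1L)
    stop("gene model '", id, "': needs at least one segment")
  if (any(segments[, 2L] <= segments[, 1L]))
    stop("gene model '", id, "': every segment must satisfy end > start")
  if (is.unsorted(segments[, 1L], strictly = TRUE) && nrow(segments) > 1L)
    stop("gene model '", id, "': segments must be sorted by ascending start")
  if (nrow(segments) > 1L &&
      any(segments[-1L, 1L] < segments[-nrow(segments), 2L]))
    stop("gene model '", id, "': segments overlap")
  structure(
    list(id = id, source = source, scaffold = scaffold, strand = strand,
         segments = segments),
    class = "gene_model"
  )
}

#' @rdname gene_model
#' @param x,m A `gene_model`.
#' @export
cds_length <- function(m) {
  stopifnot(inherits(m, "gene_model"))
  sum(m$segments[, 2L] - m$segments[, 1L])
}

#' @rdname gene_model
#' @export
exon_count <- function(m) {
  stopifnot(inherits(m, "gene_model"))
  nrow(m$segments)
}

#' @rdname gene_model
#' @export
model_span <- function(m) {
  stopifnot(inherits(m, "gene_model"))
  c(start = m$segments[1L, 1L], end = m$segments[nrow(m$segments), 2L])
}

#' @rdname gene_model
#' @param ... Ignored.
#' @export
print.gene_model <- function(x, ...) {
  sp <- model_span(x)
  cat(sprintf("<gene_model %s> %s:%d-%d(%s) %d segment(s), CDS %d nt [%s]\n",
              x$id, x$scaffold, sp[1L], sp[2L], x$strand,
              exon_count(x), cds_length(x), x$source))
  invisible(x)
}

#' Tabulate a list of gene models
#'
#' Flattens a list of [gene_model()] objects into one row per model with its
#' genomic span, exon count and CDS length; the workhorse representation for
#' vectorized clustering and filtering.
#'
#' @param models List of `gene_model` objects.
#' @return `data.frame` with columns `id`, `source`, `scaffold`, `strand`,
#'   `start`, `end`, `n_exons`, `cds_length`.
#' @export
model_table <- function(models) {
  stopifnot(is.list(models))
  if (length(models) == 0L)
    return(data.frame(id = character(), source = character(),
                      scaffold = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_exons = integer(), cds_length = integer(),
                      stringsAsFactors = FALSE))
  ids <- vapply(models, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicated gene model ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(
    id = ids,
    source = vapply(models, `[[`, "", "source"),
    scaffold = vapply(models, `[[`, "", "scaffold"),
    strand = vapply(models, `[[`, "", "strand"),
    start = vapply(models, function(m) m$segments[1L, 1L], 0L),
    end = vapply(models, function(m) m$segments[nrow(m$segments), 2L], 0L),
    n_exons = vapply(models, exon_count, 0L),
    cds_length = vapply(models, cds_length, 0L),
    stringsAsFactors = FALSE
  )
}
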