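# FASTA I/O and spliced CDS extraction.

#' Read a genome FASTA file
#'
#' Reads a FASTA file into a named character vector of upper-case sequences
#' over the alphabet `{A,C,G,T,N}`. Lower-case input is folded to upper case;
#' any other character is an error naming the record and offset.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), names(seqs)[i], bad[i]))
  }
  if (any(!nzchar(seqs)))
    stop("zero-length sequence in record '",
         names(seqs)[which(!nzchar(seqs))[1L]], "'")
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# reverse complement of an upper-case ACGTN string
revcomp <- function(s) {
  vapply(s, function(x) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
  }, "", USE.NAMES = FALSE)
}

#' Extract the spliced CDS of a gene model
#'
#' Concatenates the model's segment subsequences in ascending genomic order;
#' for minus-strand models the concatenation is reverse-complemented, so the
#' result always reads 5' to 3' in the coding direction. The result length
#' equals [cds_length()].
#'
#' @param genome Named character vector from [read_fasta()].
#' @param model A [gene_model()].
#' @return Character scalar, the spliced CDS.
#' @examples
#' g <- c(s1 = "AAACCC")
#' m <- gene_model("g1", "demo", "s1", "-", cbind(0, 6))
#' extract_cds(g, m)  # "GGGTTT"
#' @export
extract_cds <- function(genome, model) {
  stopifnot(inherits(model, "gene_model"))
  if (!model$scaffold %in% names(genome))
    stop("scaffold '", model$scaffold, "' not present in genome (model '",
         model$id, "')")
  seq <- genome[[model$scaffold]]
  if (model$segments[nrow(model$segments), 2L] > nchar(seq))
    stop("model '", model$id, "': segment out of scaffold bounds (",
         model$segments[nrow(model$segments), 2L], " > ", nchar(seq), ")")
  parts <- substring(seq, model$segments[, 1L] + 1L, model$segments[, 2L])
  cds <- paste(parts, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  cds
}
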