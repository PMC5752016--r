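# Promoter sets: fixed-length upstream regions whose 3' (right) end abuts the
# transcription start site.

#' Construct a promoter set
#'
#' A promoter set is a tibble with columns `gene_id` and `sequence`, where all
#' sequences share one fixed length (`region_length`, default taken from the
#' data) and the transcription start site abuts the 3' (right) end of every
#' sequence. Coordinates reported by the matcher are 0-based offsets from the
#' 5' (distal) end; a match's distance to the TSS is
#' `region_length - (start + width)`.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param sequence Character vector of equal-length A/C/G/T/N sequences
#'   (uppercased on input).
#' @return A tibble of class `promoter_set` with attribute `region_length`.
#' @export
promoter_set <- function(gene_id, sequence) {
  stopifnot(length(gene_id) == length(sequence), length(gene_id) >= 1L)
  gene_id <- as.character(gene_id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  widths <- nchar(sequence)
  if (length(unique(widths)) != 1L) {
    stop("all promoter sequences must have the same length")
  }
  if (any(stringi::stri_detect_regex(sequence, "[^ACGTN]"))) {
    stop("promoter sequences may only contain A, C, G, T, N")
  }
  out <- tibble::tibble(gene_id = gene_id, sequence = sequence)
  attr(out, "region_length") <- widths[1]
  class(out) <- c("promoter_set", class(out))
  out
}

#' Region length of a promoter set
#' @param promoters A `promoter_set`.
#' @return Integer sequence length shared by all promoters.
#' @export
region_length <- function(promoters) {
  rl <- attr(promoters, "region_length")
  if (is.null(rl)) rl <- unique(nchar(promoters$sequence))
  if (length(rl) != 1L) stop("promoter sequences have unequal lengths")
  as.integer(rl)
}

#' Read promoters from a FASTA file
#'
#' The record id (first whitespace-delimited token of the header) is taken as
#' the gene id; sequences are uppercased. All records must have equal length.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A [promoter_set()].
#' @export
read_promoters <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  promoter_set(ids, as.character(dss))
}

#' Write a promoter set to FASTA
#'
#' @param promoters A `promoter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  dss <- Biostrings::DNAStringSet(promoters$sequence)
  names(dss) <- promoters$gene_id
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}
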