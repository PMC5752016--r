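# Degenerate motif handling: IUPAC expansion and orientation variants.

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand a degenerate IUPAC motif into its concrete component sequences
#'
#' A query motif written in the IUPAC nucleotide alphabet (e.g. `"AAARCC"`) is
#' broken down into every concrete A/C/G/T sequence it denotes (`"AAAGCC"`,
#' `"AAAACC"`). The number of expansions is the product of the per-position
#' degeneracies.
#'
#' @param motif A single IUPAC nucleotide string (characters
#'   `ACGTRYSWKMBDHVN`, case-insensitive), length >= 1.
#' @return Character vector of distinct concrete sequences, in lexicographic
#'   order.
#' @examples
#' expand_iupac("AAARCC")
#' expand_iupac("ANT")
#' @export
expand_iupac <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L)
  motif <- toupper(motif)
  if (nchar(motif) < 1L) stop("motif must have length >= 1")
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_MAP))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC character '%s' at position %d in motif '%s'",
                 chars[bad[1]], bad[1], motif))
  }
  sets <- IUPAC_MAP[chars]
  out <- Reduce(function(acc, s) as.vector(outer(acc, s, paste0)), sets, "")
  sort(out)
}

#' Number of concrete expansions of an IUPAC motif
#'
#' @inheritParams expand_iupac
#' @return Integer: the product of per-position degeneracies.
#' @export
iupac_cardinality <- function(motif) {
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_MAP))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC character '%s' at position %d in motif '%s'",
                 chars[bad[1]], bad[1], motif))
  }
  prod(lengths(IUPAC_MAP[chars]))
}

dna_complement <- function(x) chartr("ACGT", "TGCA", x)

dna_reverse <- function(x) stringi::stri_reverse(x)

#' Orientation variants of a concrete sequence
#'
#' Returns the strings a motif can be read as when it is allowed to occur in
#' any orientation on the promoter strand: the forward sequence, its reversal
#' ("inversed"), its complement, and its reverse-complement. Palindromic or
#' self-complementary cases are deduplicated, keeping one orientation label
#' per distinct string (precedence forward > reverse > complement >
#' reverse-complement).
#'
#' @param seq A concrete A/C/G/T string.
#' @param mode `"all"` (default) for all four orientations or
#'   `"forward_only"`.
#' @return A tibble with columns `variant` and `orientation`.
#' @examples
#' orientation_variants("AAAATATCT")
#' orientation_variants("ACGT") # palindromic: collapses to 2 strings
#' @export
orientation_variants <- function(seq, mode = c("all", "forward_only")) {
  mode <- match.arg(mode)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (stringi::stri_detect_regex(seq, "[^ACGT]")) {
    stop("orientation_variants() expects a concrete A/C/G/T sequence")
  }
  if (mode == "forward_only") {
    return(tibble::tibble(variant = seq, orientation = "forward"))
  }
  out <- tibble::tibble(
    variant = c(seq, dna_reverse(seq), dna_complement(seq),
                dna_reverse(dna_complement(seq))),
    orientation = c("forward", "reverse", "complement", "reverse-complement")
  )
  out[!duplicated(out$variant), ]
}

# All concrete strings to scan for, for one (possibly degenerate) motif:
# expansion x orientation, deduplicated by string with the orientation
# precedence of orientation_variants().
motif_variants <- function(motif, mode = c("all", "forward_only")) {
  mode <- match.arg(mode)
  exps <- expand_iupac(motif)
  out <- dplyr::bind_rows(lapply(exps, orientation_variants, mode = mode))
  prec <- c("forward" = 1L, "reverse" = 2L, "complement" = 3L,
            "reverse-complement" = 4L)
  out <- out[order(prec[out$orientation], out$variant), ]
  out[!duplicated(out$variant), ]
}

#' Parse a query line into its member motifs
#'
#' A query is either a single IUPAC motif or a comma-separated pair of motifs
#' (a candidate CRE module). Whitespace is trimmed and members uppercased.
#'
#' @param query Single query string, e.g. `"AAAATATCT"` or
#'   `"CCACGTGG,ACAGTACT"`.
#' @return Character vector of 1 or 2 member motifs.
#' @export
parse_query <- function(query) {
  stopifnot(is.character(query), length(query) == 1L)
  members <- toupper(trimws(strsplit(query, ",", fixed = TRUE)[[1]]))
  members <- members[nzchar(members)]
  if (length(members) < 1L || length(members) > 2L) {
    stop(sprintf("query '%s' must contain one motif or a comma-separated pair", query))
  }
  members
}

#' Read a motif/query list from a text file
#'
#' One query per line; a comma separates the members of a pair; `#` starts a
#' comment; blank lines are ignored.
#'
#' @param path Path to a UTF-8 text file.
#' @return Character vector of query strings.
#' @export
read_query_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
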