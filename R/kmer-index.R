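# K-mer indexed matching of concrete motif variants against a promoter set.
# Variants seed the index by their first k bases and candidate sites are
# verified by direct string comparison, so indexed and naive scans agree
# exactly. Variants shorter than k fall back to the naive scan.

#' Build a k-mer index over a promoter set
#'
#' Every k-mer occurrence of every promoter (including overlapping ones)
#' appears exactly once in the postings. The index accelerates
#' [find_matches()]; results are identical to a naive scan.
#'
#' @param promoters A [promoter_set()].
#' @param k Word size, `1 <= k <= region_length`. Default 5, the shortest
#'   random-background motif length.
#' @return An object of class `kmer_index`.
#' @export
build_kmer_index <- function(promoters, k = 5L) {
  L <- region_length(promoters)
  k <- as.integer(k)
  if (k < 1L || k > L) stop("k must be between 1 and the region length")
  n <- nrow(promoters)
  n_pos <- L - k + 1L
  starts <- seq_len(n_pos)
  kmers <- unlist(lapply(promoters$sequence, function(s) {
    substring(s, starts, starts + k - 1L)
  }), use.names = FALSE)
  gene <- rep(seq_len(n), each = n_pos)
  offset <- rep.int(starts - 1L, n)
  ord <- order(kmers, gene, offset, method = "radix")
  kmers <- kmers[ord]
  post <- data.frame(gene = gene[ord], offset = offset[ord])
  runs <- rle(kmers)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  postings <- structure(
    mapply(function(a, b) post[a:b, , drop = FALSE], idx_start, idx_end,
           SIMPLIFY = FALSE),
    names = runs$values
  )
  structure(
    list(k = k, postings = postings, gene_id = promoters$gene_id,
         sequence = promoters$sequence, region_length = L),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d over %d promoters (L=%d), %d distinct k-mers\n",
              x$k, length(x$gene_id), x$region_length, length(x$postings)))
  invisible(x)
}

# Indexed scan for one concrete variant: returns data.frame(gene, offset),
# 0-based offsets. Exact, verified matches only.
scan_indexed <- function(index, variant) {
  w <- nchar(variant)
  if (w < index$k) return(scan_naive_idx(index$sequence, variant))
  key <- substr(variant, 1L, index$k)
  post <- index$postings[[key]]
  if (is.null(post)) return(data.frame(gene = integer(), offset = integer()))
  keep <- post$offset + w <= index$region_length
  post <- post[keep, , drop = FALSE]
  if (nrow(post) == 0L) return(post)
  hit <- substring(index$sequence[post$gene], post$offset + 1L, post$offset + w) == variant
  post[hit, , drop = FALSE]
}

# Naive overlapping fixed-string scan; the reference arm of the
# indexed-equals-naive invariant. 0-based offsets.
scan_naive_idx <- function(sequences, variant) {
  loc <- stringi::stri_locate_all_fixed(sequences, variant, overlap = TRUE)
  n_hit <- vapply(loc, function(m) sum(!is.na(m[, 1])), integer(1))
  gene <- rep(seq_along(sequences), n_hit)
  offset <- unlist(lapply(loc, function(m) m[!is.na(m[, 1]), 1]), use.names = FALSE)
  data.frame(gene = gene, offset = as.integer(offset) - 1L)
}

#' Match a motif query against a promoter set
#'
#' Expands the (possibly degenerate) motif, generates orientation variants,
#' and reports every occurrence of every variant in every promoter,
#' overlapping occurrences included. With an index the result is identical to
#' the naive scan. Identical `(gene, start, variant)` records arising from
#' palindromic variants are deduplicated.
#'
#' @param motif A single IUPAC motif (no comma; see [parse_query()] for
#'   pairs).
#' @param promoters A [promoter_set()].
#' @param index Optional [build_kmer_index()] result for `promoters`.
#' @param mode `"all"` orientations (default) or `"forward_only"`.
#' @return A tibble of match records: `gene_id`, `start` (0-based offset from
#'   the 5' end), `variant`, `orientation`, `width`, `dist_tss` (bases between
#'   the match's TSS-proximal edge and the TSS), ordered by gene id then
#'   start.
#' @export
find_matches <- function(motif, promoters, index = NULL,
                         mode = c("all", "forward_only")) {
  mode <- match.arg(mode)
  L <- region_length(promoters)
  empty <- tibble::tibble(gene_id = character(), start = integer(),
                          variant = character(), orientation = character(),
                          width = integer(), dist_tss = integer())
  if (nchar(motif) > L) {
    warning(sprintf("motif '%s' is longer than the promoter region (%d bp)", motif, L))
    return(empty)
  }
  vars <- motif_variants(motif, mode = mode)
  recs <- lapply(seq_len(nrow(vars)), function(i) {
    v <- vars$variant[i]
    hit <- if (is.null(index)) scan_naive_idx(promoters$sequence, v) else scan_indexed(index, v)
    if (nrow(hit) == 0L) return(NULL)
    tibble::tibble(gene_id = promoters$gene_id[hit$gene], start = hit$offset,
                   variant = v, orientation = vars$orientation[i])
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) return(empty)
  out <- out[!duplicated(out[c("gene_id", "start", "variant")]), ]
  out$width <- nchar(out$variant)
  out$dist_tss <- L - (out$start + out$width)
  out[order(out$gene_id, out$start, out$variant), ]
}

#' Genes matched by a query
#'
#' For a single motif, the set of gene ids with at least one occurrence of any
#' expansion/orientation (union over component CREs). For a comma-separated
#' pair, genes containing at least one occurrence of *both* members
#' (intersection of the per-member gene sets).
#'
#' @param query Query string (single motif or `"A,B"` pair).
#' @inheritParams find_matches
#' @return Character vector of gene ids, sorted.
#' @export
matched_genes <- function(query, promoters, index = NULL,
                          mode = c("all", "forward_only")) {
  mode <- match.arg(mode)
  members <- parse_query(query)
  sets <- lapply(members, function(m) {
    unique(find_matches(m, promoters, index = index, mode = mode)$gene_id)
  })
  sort(Reduce(intersect, sets))
}

# Orientation variant strings of a concrete sequence, without the tibble
# bookkeeping of motif_variants(); used on the hot background path.
concrete_variants <- function(s, mode = "all") {
  if (mode == "forward_only") return(s)
  unique(c(s, stringi::stri_reverse(s), chartr("ACGT", "TGCA", s),
           stringi::stri_reverse(chartr("ACGT", "TGCA", s))))
}

# Fast presence path used by the background engine: integer gene indices with
# >= 1 occurrence of any variant of a *concrete* motif.
match_gene_idx <- function(index, variants) {
  idx <- integer(0)
  for (v in variants) {
    idx <- c(idx, scan_indexed(index, v)$gene)
  }
  unique(idx)
}
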