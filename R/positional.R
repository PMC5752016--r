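# Positional features of candidate CRE pairs: member spacing vs a stochastic
# null (two-sample KS), member order relative to the TSS (exact binomial),
# and Bowley's quartile skewness of module positions.

#' Per-promoter placements of a CRE pair
#'
#' For every promoter containing at least one occurrence of both members,
#' records: the closest-occurrence spacing (minimum over occurrence pairs of
#' the absolute difference of TSS-proximal edge distances), the module
#' position (smallest distance of either member to the TSS), and which member
#' is TSS-proximal (from each member's TSS-nearest occurrence; `NA` and
#' dropped from the order test on exact ties).
#'
#' @param matches_a,matches_b Match tibbles from [find_matches()] for the two
#'   members, over the same promoter set.
#' @return A tibble with columns `gene_id`, `distance`, `crm_dist_tss`,
#'   `proximal` (`"a"`, `"b"`, or `NA`).
#' @export
observed_placements <- function(matches_a, matches_b) {
  common <- intersect(unique(matches_a$gene_id), unique(matches_b$gene_id))
  if (length(common) == 0L) {
    return(tibble::tibble(gene_id = character(), distance = integer(),
                          crm_dist_tss = integer(), proximal = character()))
  }
  da <- split(matches_a$dist_tss, matches_a$gene_id)
  db <- split(matches_b$dist_tss, matches_b$gene_id)
  rows <- lapply(common, function(g) {
    a <- da[[g]]; b <- db[[g]]
    dist <- min(abs(outer(a, b, "-")))
    amin <- min(a); bmin <- min(b)
    prox <- if (amin < bmin) "a" else if (bmin < amin) "b" else NA_character_
    tibble::tibble(gene_id = g, distance = dist,
                   crm_dist_tss = min(amin, bmin), proximal = prox)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$gene_id), ]
}

#' Stochastic null distribution of member spacings
#'
#' Emulates pairs placed at random: per iteration, `n_a = max(1,
#' round(rate_a))` and `n_b` likewise positions are drawn uniformly on
#' `[0, region_length)` and the smallest absolute pairwise difference is
#' recorded. Rates are expected occurrences per promoter (total occurrences /
#' total promoters); expected counts below 1 are floored at 1, since a
#' co-occurrence requires at least one occurrence of each member.
#'
#' @param rate_a,rate_b Expected occurrences per promoter for each member
#'   (> 0).
#' @param region_length Promoter length in bp (default 1000).
#' @param iters Number of iterations (default 10000).
#' @return Numeric vector of `iters` expected spacings.
#' @export
null_distance_distribution <- function(rate_a, rate_b, region_length = 1000,
                                       iters = 10000L) {
  stopifnot(rate_a > 0, rate_b > 0, iters >= 1L)
  n_a <- max(1L, as.integer(round(rate_a)))
  n_b <- max(1L, as.integer(round(rate_b)))
  if (n_a == 1L && n_b == 1L) {
    return(abs(stats::runif(iters, 0, region_length) -
               stats::runif(iters, 0, region_length)))
  }
  a <- matrix(stats::runif(iters * n_a, 0, region_length), iters, n_a)
  b <- matrix(stats::runif(iters * n_b, 0, region_length), iters, n_b)
  vapply(seq_len(iters), function(i) min(abs(outer(a[i, ], b[i, ], "-"))),
         numeric(1))
}

#' Spacing preference test
#'
#' Two-sided two-sample Kolmogorov-Smirnov test of the observed spacings
#' against the stochastic null sample. With fewer than 3 observed values the
#' p-value is not computed (`NA`).
#'
#' @param observed Observed spacings (bp).
#' @param null_sample Null spacings from [null_distance_distribution()].
#' @return KS p-value, or `NA` when not computed.
#' @export
distance_test <- function(observed, null_sample) {
  observed <- observed[!is.na(observed)]
  if (length(observed) < 3L) return(NA_real_)
  if (length(unique(null_sample)) < 2L) stop("degenerate null sample: all values equal")
  suppressWarnings(stats::ks.test(observed, null_sample)$p.value)
}

#' Order preference test
#'
#' Exact binomial test of which pair member lies TSS-proximal, under the null
#' that each order is equally likely (p = q = 0.5):
#' `p = min(1, 2 * sum_{i=X..n} C(n, i) 0.5^n)`, the doubled upper tail.
#'
#' @param n Number of co-occurring promoters with a defined order.
#' @param x Count of the more frequent order (`x >= n - x`).
#' @return Two-sided p-value, or `NA` when `n = 0`.
#' @export
order_test <- function(n, x) {
  if (n == 0L) return(NA_real_)
  stopifnot(n >= 1L, x >= 0L, x <= n)
  if (x < n - x) stop("x must count the more frequent order (x >= n - x)")
  min(1, 2 * stats::pbinom(x - 1L, n, 0.5, lower.tail = FALSE))
}

#' Bowley's quartile coefficient of skewness
#'
#' `S = (Q3 + Q1 - 2 Q2) / (Q3 - Q1)` with type-7 quartiles; bounded in
#' `[-1, 1]`. Needs at least 4 values and `Q3 > Q1`; otherwise `NA`.
#'
#' @param positions Numeric vector.
#' @return `S` in `[-1, 1]`, or `NA` when not computed.
#' @export
bowley_skewness <- function(positions) {
  positions <- positions[!is.na(positions)]
  if (length(positions) < 4L) return(NA_real_)
  q <- stats::quantile(positions, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (q[3] <= q[1]) return(NA_real_)
  (q[3] + q[1] - 2 * q[2]) / (q[3] - q[1])
}

#' The three positional statistics of a CRE pair
#'
#' Matches both members, derives per-promoter placements, and bundles the
#' order-test p-value, the distance-test p-value (against a freshly simulated
#' null), and Bowley's skewness of module positions. Positions are measured
#' on the promoter coordinate scale (TSS at `region_length`), so
#' TSS-proximal clustering yields negative skewness. With fewer than 2
#' co-occurring promoters all three statistics are `NA`.
#'
#' @param query A comma-separated pair query, e.g. `"CCACGTGGC,ACAGTACT"`.
#' @param promoters A [promoter_set()].
#' @param index Optional [build_kmer_index()].
#' @param mode Orientation mode (default `"all"`).
#' @param iters Null-simulation iterations (default 10000).
#' @return One-row tibble: `query`, `n_promoters` (co-occurring), `n_ordered`
#'   (with defined order), `order_p`, `distance_p`, `bowley`.
#' @export
pair_positional_stats <- function(query, promoters, index = NULL,
                                  mode = c("all", "forward_only"),
                                  iters = 10000L) {
  mode <- match.arg(mode)
  members <- parse_query(query)
  if (length(members) != 2L) stop("positional statistics require a pair query")
  if (is.null(index)) index <- build_kmer_index(promoters, k = 5L)
  ma <- find_matches(members[1], promoters, index = index, mode = mode)
  mb <- find_matches(members[2], promoters, index = index, mode = mode)
  pl <- observed_placements(ma, mb)
  L <- region_length(promoters)
  n_prom <- nrow(pl)
  if (n_prom < 2L) {
    return(tibble::tibble(query = query, n_promoters = n_prom,
                          n_ordered = sum(!is.na(pl$proximal)),
                          order_p = NA_real_, distance_p = NA_real_,
                          bowley = NA_real_))
  }
  ordered <- pl$proximal[!is.na(pl$proximal)]
  n_ord <- length(ordered)
  x <- if (n_ord > 0L) max(sum(ordered == "a"), sum(ordered == "b")) else 0L
  op <- if (n_ord >= 2L) order_test(n_ord, x) else NA_real_
  rate_a <- nrow(ma) / nrow(promoters)
  rate_b <- nrow(mb) / nrow(promoters)
  nd <- null_distance_distribution(rate_a, rate_b, region_length = L, iters = iters)
  dp <- distance_test(pl$distance, nd)
  bw <- bowley_skewness(L - pl$crm_dist_tss)
  tibble::tibble(query = query, n_promoters = n_prom, n_ordered = n_ord,
                 order_p = op, distance_p = dp, bowley = bw)
}
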