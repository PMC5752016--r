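# The screening engine: random-motif backgrounds, per-category standard
# deviation thresholds, candidate calls with majority voting over background
# replicates, and pair enumeration.

#' Draw a random CRE
#'
#' A concrete motif with length uniform in `[len_min, len_max]` and bases
#' i.i.d. from `base_probs`. Uses the current R random number generator.
#'
#' @param len_min,len_max Length bounds (defaults 5 and 8, the random
#'   background used throughout).
#' @param base_probs Probabilities for A, C, G, T (default uniform).
#' @return A single concrete motif string.
#' @export
random_cre <- function(len_min = 5L, len_max = 8L,
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(len_min <= len_max, len_min >= 1L)
  len <- if (len_min == len_max) len_min else sample(len_min:len_max, 1L)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = base_probs),
        collapse = "")
}

# Integer category code (1..K) per promoter row; NA when the promoter's gene
# is absent from the catalog.
catalog_codes <- function(promoters, catalog) {
  as.integer(catalog$category[match(promoters$gene_id, catalog$gene_id)])
}

#' Build a randomized background model
#'
#' Draws `n_random` random CREs per background replicate, computes each CRE's
#' distribution of expression maxima (DEM) over the catalog, and records the
#' per-category mean and standard deviation of those DEMs, for
#' `n_backgrounds` independent replicates. The per-category standard
#' deviations define the candidate thresholds (in sd multiples); the majority
#' vote over replicates damps the run-to-run variation of a single random
#' background. Draws that match no cataloged gene have no defined DEM and are
#' replaced (their count is recorded).
#'
#' @param promoters A [promoter_set()].
#' @param catalog An [expression_catalog()] sharing gene ids with `promoters`.
#' @param n_random Random CREs per background replicate (default 100).
#' @param n_backgrounds Number of background replicates (default 100).
#' @param len_range Random CRE length range (default `c(5, 8)`).
#' @param mode Orientation mode passed to the matcher (default `"all"`).
#' @param index Optional prebuilt [build_kmer_index()]; built if missing.
#' @param base_probs Base composition of random CREs (default uniform).
#' @return An object of class `background_model`: per-replicate matrices of
#'   per-category means and sds, the catalog background, and draw metadata.
#' @export
build_background_model <- function(promoters, catalog, n_random = 100L,
                                   n_backgrounds = 100L, len_range = c(5L, 8L),
                                   mode = c("all", "forward_only"),
                                   index = NULL,
                                   base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  mode <- match.arg(mode)
  if (is.null(index)) index <- build_kmer_index(promoters, k = min(len_range[1], 8L))
  codes <- catalog_codes(promoters, catalog)
  n_cat <- nlevels(catalog$category)
  bg <- background_distribution(catalog)
  cap <- 50L * n_random * n_backgrounds
  n_rejected <- 0L
  draws <- 0L
  sd_mat <- matrix(NA_real_, n_backgrounds, n_cat)
  mean_mat <- matrix(NA_real_, n_backgrounds, n_cat)
  for (b in seq_len(n_backgrounds)) {
    dems <- matrix(NA_real_, n_random, n_cat)
    i <- 0L
    while (i < n_random) {
      if (draws >= cap) stop("draw cap reached while building the background model")
      draws <- draws + 1L
      cre <- random_cre(len_range[1], len_range[2], base_probs = base_probs)
      g <- match_gene_idx(index, concrete_variants(cre, mode))
      cc <- codes[g]
      cc <- cc[!is.na(cc)]
      if (length(cc) == 0L) {
        n_rejected <- n_rejected + 1L
        next
      }
      i <- i + 1L
      dems[i, ] <- dem_pct(cc, n_cat)
    }
    mean_mat[b, ] <- colMeans(dems)
    sd_mat[b, ] <- apply(dems, 2L, stats::sd)
  }
  colnames(mean_mat) <- colnames(sd_mat) <- levels(catalog$category)
  structure(
    list(mean = mean_mat, sd = sd_mat, n_random = n_random,
         n_backgrounds = n_backgrounds, len_range = len_range,
         background = bg, n_rejected = n_rejected, mode = mode),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> %d replicates x %d random CREs (lengths %d-%d), %d rejected draws\n",
              x$n_backgrounds, x$n_random, x$len_range[1], x$len_range[2], x$n_rejected))
  cat("per-category sd (mean over replicates):\n")
  print(round(colMeans(x$sd), 3))
  invisible(x)
}

# sd-unit deviation of one deviation vector against one replicate's sd vector.
# Zero sd: 0 when the deviation is (numerically) zero there, +Inf otherwise.
sd_ratio <- function(dev, sd_vec) {
  r <- dev / sd_vec
  zero <- sd_vec == 0
  r[zero] <- ifelse(dev[zero] < 1e-9, 0, Inf)
  r
}

#' Evaluate one query against the background model
#'
#' Computes the query's DEM, its absolute per-category deviation from the
#' catalog background in units of each background replicate's per-category
#' sd, and the majority vote: a replicate "flags" the query when any
#' category's deviation reaches `threshold_sd`; the query is a candidate when
#' a strict majority of replicates flag it and it matches at least
#' `min_matches` promoters.
#'
#' @param query Single motif or comma-separated pair (genes must contain both
#'   members).
#' @param promoters,catalog,index,mode As in [build_background_model()].
#' @param model A [build_background_model()] result.
#' @param threshold_sd Deviation threshold in sd multiples (default 1).
#' @param min_matches Minimum matching promoters (default 20).
#' @return An object of class `candidate_call`; see [tidy.candidate_call()].
#' @export
evaluate_query <- function(query, promoters, catalog, model,
                           threshold_sd = 1, min_matches = 20L,
                           mode = NULL, index = NULL) {
  if (is.null(mode)) mode <- model$mode
  if (is.null(index)) index <- build_kmer_index(promoters, k = 5L)
  genes <- matched_genes(query, promoters, index = index, mode = mode)
  evaluate_gene_set(query, genes, catalog, model, threshold_sd, min_matches)
}

# Core decision on a precomputed matched-gene set (shared by the mutational
# scan and the pair sweep, which reuse match results).
evaluate_gene_set <- function(query, genes, catalog, model,
                              threshold_sd = 1, min_matches = 20L) {
  n_cat <- nlevels(catalog$category)
  d <- dem(genes, catalog)
  n_used <- attr(d, "n_genes")
  B <- model$n_backgrounds
  bg <- model$background$pct
  call <- list(query = query, n_matches = length(genes), n_used = n_used,
               dem = d, background = model$background,
               threshold_sd = threshold_sd, min_matches = min_matches,
               n_backgrounds = B)
  if (n_used == 0L) {
    call <- c(call, list(votes = 0L, candidate = FALSE,
                         flagged_categories = character(),
                         deviation = NULL, reason = "no cataloged matches"))
    class(call) <- "candidate_call"
    return(call)
  }
  dev <- abs(d$pct - bg)
  ratios <- t(vapply(seq_len(B), function(b) sd_ratio(dev, model$sd[b, ]),
                     numeric(n_cat)))               # B x K
  flags_cat <- ratios >= threshold_sd               # B x K
  flags <- rowSums(flags_cat) > 0L
  votes <- sum(flags)
  cat_votes <- colSums(flags_cat)
  flagged <- levels(catalog$category)[cat_votes > B / 2]
  enough <- length(genes) >= min_matches
  candidate <- enough && votes > B / 2
  reason <- if (!enough) "insufficient occurrences" else NA_character_
  deviation <- tibble::tibble(
    category = levels(catalog$category),
    dem_pct = d$pct, background_pct = bg,
    direction = sign(d$pct - bg),
    median_sd_ratio = apply(ratios, 2L, stats::median),
    vote_frac = cat_votes / B
  )
  call <- c(call, list(votes = votes, candidate = candidate,
                       flagged_categories = flagged,
                       deviation = deviation, reason = reason))
  class(call) <- "candidate_call"
  call
}

#' @export
print.candidate_call <- function(x, ...) {
  cat(sprintf("<candidate_call> '%s': %s (%d/%d background votes, %d matching promoters)\n",
              x$query, if (x$candidate) "CANDIDATE" else "not a candidate",
              x$votes, x$n_backgrounds, x$n_matches))
  if (length(x$flagged_categories)) {
    cat("flagged categories:", paste(x$flagged_categories, collapse = ", "), "\n")
  }
  if (!is.null(x$reason) && !is.na(x$reason)) cat("reason:", x$reason, "\n")
  invisible(x)
}

#' Tidy a candidate call into its per-category deviation table
#'
#' @param x A `candidate_call`.
#' @param ... Unused.
#' @return A tibble with one row per category: DEM and background
#'   percentages, deviation direction, the median sd-unit deviation over
#'   background replicates, and the per-category vote fraction.
#' @export
tidy.candidate_call <- function(x, ...) {
  if (is.null(x$deviation)) {
    return(tibble::tibble(category = character(), dem_pct = double(),
                          background_pct = double(), direction = double(),
                          median_sd_ratio = double(), vote_frac = double()))
  }
  x$deviation
}

#' One-row summary of a candidate call
#' @inheritParams tidy.candidate_call
#' @return A one-row tibble.
#' @export
glance.candidate_call <- function(x, ...) {
  tibble::tibble(query = x$query, n_matches = x$n_matches,
                 candidate = x$candidate, votes = x$votes,
                 n_backgrounds = x$n_backgrounds,
                 flagged = paste(x$flagged_categories, collapse = ","),
                 max_sd_ratio = if (is.null(x$deviation)) NA_real_ else max(x$deviation$median_sd_ratio),
                 reason = if (is.null(x$reason)) NA_character_ else x$reason)
}

#' Screen a set of queries
#'
#' Evaluates each query against one background model and returns the calls as
#' a tibble (one row per query).
#'
#' @param queries Character vector of queries (single motifs or pairs).
#' @inheritParams evaluate_query
#' @return A tibble with the [glance.candidate_call()] columns.
#' @export
screen_queries <- function(queries, promoters, catalog, model,
                           threshold_sd = 1, min_matches = 20L,
                           mode = NULL, index = NULL) {
  if (is.null(mode)) mode <- model$mode
  if (is.null(index)) index <- build_kmer_index(promoters, k = 5L)
  dplyr::bind_rows(lapply(queries, function(q) {
    glance(evaluate_query(q, promoters, catalog, model,
                          threshold_sd = threshold_sd,
                          min_matches = min_matches, mode = mode, index = index))
  }))
}

#' Quartile dispersion coefficient
#'
#' `(Q3 - Q1) / (Q3 + Q1)` with type-7 (linearly interpolated) quartiles; the
#' reproducibility measure for candidate counts across repeated runs.
#'
#' @param x Numeric vector (needs >= 2 values; otherwise `NA`).
#' @return A single number, or `NA` when undefined (including `Q3 + Q1 = 0`).
#' @export
quartile_dispersion <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  if (sum(q) == 0) return(NA_real_)
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Repeat a query screen and measure its reproducibility
#'
#' Runs [screen_queries()] `n_repeats` times, each with a freshly drawn
#' background model, and reports the candidate-set overlap
#' (`|intersection| / |union|` across repeats) and the quartile dispersion
#' coefficient of the candidate counts.
#'
#' @inheritParams screen_queries
#' @param n_repeats Number of independent repeats (>= 1).
#' @param n_random,n_backgrounds,len_range Background-model settings.
#' @return An object of class `query_screen` with per-repeat results; see
#'   [tidy.query_screen()] and [glance.query_screen()].
#' @export
run_query_set <- function(queries, promoters, catalog, n_repeats = 1L,
                          threshold_sd = 1, min_matches = 20L,
                          n_random = 100L, n_backgrounds = 100L,
                          len_range = c(5L, 8L),
                          mode = c("all", "forward_only"), index = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_repeats >= 1L)
  if (is.null(index)) index <- build_kmer_index(promoters, k = min(len_range[1], 8L))
  reps <- lapply(seq_len(n_repeats), function(r) {
    model <- build_background_model(promoters, catalog, n_random = n_random,
                                    n_backgrounds = n_backgrounds,
                                    len_range = len_range, mode = mode,
                                    index = index)
    res <- screen_queries(queries, promoters, catalog, model,
                          threshold_sd = threshold_sd,
                          min_matches = min_matches, mode = mode, index = index)
    res$repeat_id <- r
    res
  })
  results <- dplyr::bind_rows(reps)
  cand_sets <- lapply(reps, function(r) r$query[r$candidate])
  counts <- lengths(cand_sets)
  uni <- Reduce(union, cand_sets)
  overlap <- if (length(uni) == 0L) 1 else length(Reduce(intersect, cand_sets)) / length(uni)
  structure(
    list(results = results, candidate_sets = cand_sets,
         overlap = overlap,
         qdc = if (n_repeats > 1L) quartile_dispersion(counts) else NA_real_,
         n_repeats = n_repeats),
    class = "query_screen"
  )
}

#' @export
print.query_screen <- function(x, ...) {
  cat(sprintf("<query_screen> %d repeat(s); candidate counts: %s\n",
              x$n_repeats, paste(lengths(x$candidate_sets), collapse = ", ")))
  cat(sprintf("overlap %.1f%%; quartile dispersion %s\n", 100 * x$overlap,
              if (is.na(x$qdc)) "undefined (single repeat)" else sprintf("%.4f", x$qdc)))
  invisible(x)
}

#' Per-query summary across repeats
#' @param x A `query_screen`.
#' @param ... Unused.
#' @return A tibble: per query, the fraction of repeats calling it candidate
#'   and the mean votes.
#' @export
tidy.query_screen <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$results, .data$query),
                   candidate_frac = mean(.data$candidate),
                   mean_votes = mean(.data$votes),
                   n_matches = .data$n_matches[1],
                   .groups = "drop")
}

#' One-row reproducibility summary of a repeated screen
#' @inheritParams tidy.query_screen
#' @return A one-row tibble with `n_repeats`, `overlap`, `qdc`, and the mean
#'   candidate count.
#' @export
glance.query_screen <- function(x, ...) {
  tibble::tibble(n_repeats = x$n_repeats, overlap = x$overlap, qdc = x$qdc,
                 mean_candidates = mean(lengths(x$candidate_sets)))
}

#' Enumerate all unordered CRE pairs, homotypic pairs included
#'
#' For `m` deduplicated motifs this yields `m (m + 1) / 2` pairs in
#' deterministic lexicographic order.
#'
#' @param motifs Character vector of motifs (deduplicated and uppercased
#'   internally).
#' @return A tibble with columns `a`, `b` (`a <= b`) and `query` (`"a,b"`).
#' @export
enumerate_pairs <- function(motifs) {
  x <- sort(unique(toupper(motifs)))
  m <- length(x)
  i <- rep.int(seq_len(m), times = m - seq_len(m) + 1L)
  j <- sequence(m - seq_len(m) + 1L, from = seq_len(m))
  tibble::tibble(a = x[i], b = x[j], query = paste(x[i], x[j], sep = ","))
}

#' Count the unordered pairs of a motif list without materializing them
#'
#' @inheritParams enumerate_pairs
#' @return `m (m + 1) / 2` where `m` is the number of distinct motifs.
#' @export
count_pairs <- function(motifs) {
  m <- length(unique(toupper(motifs)))
  m * (m + 1) / 2
}
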