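# Mutational scan of a CRE pair: sample unique mutants at 0..max_mutations
# Hamming distance, re-evaluate each against the background model, and
# profile the surviving variants per position.

mutate_pair_string <- function(concat, n_mut) {
  if (n_mut == 0L) return(concat)
  chars <- strsplit(concat, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Mutational scan of a CRE pair
#'
#' Samples `n_mutants` unique mutant pairs (per mutant, a mutation count
#' drawn uniformly in `[0, max_mutations]` and that many positions changed to
#' a different base; duplicates rejected), evaluates each with the same
#' background model and thresholds as the original, and labels as "survivor"
#' any mutant that is a candidate whose flagged categories still include all
#' of the original's flagged categories.
#'
#' @param pair A concrete pair query, e.g. `"AAAATATCT,ACACGTG"`.
#' @param promoters,catalog,model,threshold_sd,min_matches,mode,index As in
#'   [evaluate_query()].
#' @param n_mutants Number of unique mutants to sample (capped with a warning
#'   at the size of the reachable mutant space).
#' @param max_mutations Maximum Hamming distance from the original pair
#'   (default 16).
#' @return An object of class `mutation_scan`: a tibble of mutants
#'   (`member_a`, `member_b`, `n_mutations`, `n_matches`, `candidate`,
#'   `survivor`) plus the original call.
#' @export
mutation_scan <- function(pair, promoters, catalog, model,
                          n_mutants = 200L, max_mutations = 16L,
                          threshold_sd = 1, min_matches = 20L,
                          mode = NULL, index = NULL) {
  if (is.null(mode)) mode <- model$mode
  if (is.null(index)) index <- build_kmer_index(promoters, k = 5L)
  members <- parse_query(pair)
  if (length(members) != 2L) stop("mutation_scan() requires a pair query")
  if (any(stringi::stri_detect_regex(members, "[^ACGT]"))) {
    stop("pair members must be concrete A/C/G/T sequences")
  }
  w_a <- nchar(members[1])
  total <- w_a + nchar(members[2])
  max_mutations <- min(max_mutations, total)
  # reachable mutant space: sum over m of C(total, m) * 3^m
  space <- sum(choose(total, 0:max_mutations) * 3^(0:max_mutations))
  if (n_mutants > space) {
    warning(sprintf("requested %d mutants but only %.0f are reachable; capping",
                    n_mutants, space))
    n_mutants <- as.integer(space)
  }
  concat0 <- paste0(members[1], members[2])
  seen <- character(0)
  tries <- 0L
  while (length(seen) < n_mutants && tries < 100L * n_mutants) {
    tries <- tries + 1L
    m <- sample(0:max_mutations, 1L)
    cand <- mutate_pair_string(concat0, m)
    if (!cand %in% seen) seen <- c(seen, cand)
  }
  orig <- evaluate_query(pair, promoters, catalog, model,
                         threshold_sd = threshold_sd,
                         min_matches = min_matches, mode = mode, index = index)
  flagged0 <- orig$flagged_categories
  rows <- lapply(seen, function(s) {
    a <- substr(s, 1L, w_a)
    b <- substr(s, w_a + 1L, total)
    q <- paste(a, b, sep = ",")
    cl <- evaluate_query(q, promoters, catalog, model,
                         threshold_sd = threshold_sd,
                         min_matches = min_matches, mode = mode, index = index)
    n_mut <- sum(strsplit(s, "")[[1]] != strsplit(concat0, "")[[1]])
    tibble::tibble(member_a = a, member_b = b, n_mutations = n_mut,
                   n_matches = cl$n_matches, candidate = cl$candidate,
                   survivor = cl$candidate && all(flagged0 %in% cl$flagged_categories))
  })
  structure(
    list(pair = pair, members = members, mutants = dplyr::bind_rows(rows),
         original = orig, max_mutations = max_mutations),
    class = "mutation_scan"
  )
}

#' @export
print.mutation_scan <- function(x, ...) {
  cat(sprintf("<mutation_scan> '%s': %d mutants (<= %d mutations), %d survivors\n",
              x$pair, nrow(x$mutants), x$max_mutations, sum(x$mutants$survivor)))
  invisible(x)
}

#' Tidy a mutational scan
#' @param x A `mutation_scan`.
#' @param ... Unused.
#' @return The mutant tibble.
#' @export
tidy.mutation_scan <- function(x, ...) x$mutants

#' Per-position importance profile of a member over scan survivors
#'
#' For each position of the original member, importance is `1 - (fraction of
#' survivors whose base at that position differs from the original)`; the
#' base-frequency table over survivors is returned alongside (rows sum to 1).
#'
#' @param original The member's original concrete sequence.
#' @param survivors Character vector of that member's sequence in the
#'   surviving mutants (>= 1).
#' @return A tibble with one row per position: `position`, `original_base`,
#'   `importance`, and base frequencies `A`, `C`, `G`, `T`.
#' @export
survivor_pwm <- function(original, survivors) {
  stopifnot(length(survivors) >= 1L)
  if (any(nchar(survivors) != nchar(original))) {
    stop("survivors must have the member's original length")
  }
  w <- nchar(original)
  orig <- strsplit(original, "", fixed = TRUE)[[1]]
  mat <- do.call(rbind, strsplit(survivors, "", fixed = TRUE))
  freq <- t(vapply(seq_len(w), function(p) {
    tab <- table(factor(mat[, p], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / length(survivors)
  }, numeric(4)))
  colnames(freq) <- c("A", "C", "G", "T")
  imp <- vapply(seq_len(w), function(p) mean(mat[, p] == orig[p]), numeric(1))
  tibble::as_tibble(cbind(
    tibble::tibble(position = seq_len(w), original_base = orig, importance = imp),
    tibble::as_tibble(freq)
  ))
}
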