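# Evolutionary training of two-class feedforward networks that group
# candidate CRE pairs by their three positional statistics. A network has one
# sigmoid hidden layer and a single Heaviside output neuron; training evolves
# weights and biases only (never the structure) by selection, mutation and
# crossover, in rounds within cycles; each cycle contributes the best network
# found, and later cycles are forced toward positives not yet categorized.

#' Default training parameters for the network evolver
#'
#' All user-overridable. `n_hidden` hidden neurons; `population` networks per
#' round, of which the `top_k` best are kept, `n_fresh` are new random
#' networks and the rest are mutants/crosses of the best; `patience` stagnant
#' rounds end a cycle; weights and biases are initialized uniformly on
#' `[-init_range, init_range]`; `step` is the incremental mutation size;
#' `max_rounds` and `max_cycles` are safety caps.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of parameters.
#' @export
cng_params <- function(...) {
  p <- list(n_hidden = 3L, population = 50L, top_k = 10L, n_fresh = 10L,
            patience = 15L, init_range = 5, step = 0.1,
            max_rounds = 400L, max_cycles = 50L)
  o <- list(...)
  stopifnot(all(names(o) %in% names(p)))
  p[names(o)] <- o
  p
}

#' Create a random two-class network
#'
#' @param n_hidden Number of hidden neurons.
#' @param init_range Weights/biases drawn uniformly on
#'   `[-init_range, init_range]`.
#' @return An object of class `cng_network`: hidden weights `w`
#'   (`n_hidden x 3`), hidden biases `b_h`, output weights `v`, output bias
#'   `b_o`.
#' @export
cng_network <- function(n_hidden = 3L, init_range = 5) {
  structure(
    list(w = matrix(stats::runif(3L * n_hidden, -init_range, init_range), n_hidden, 3L),
         b_h = stats::runif(n_hidden, -init_range, init_range),
         v = stats::runif(n_hidden, -init_range, init_range),
         b_o = stats::runif(1L, -init_range, init_range)),
    class = "cng_network"
  )
}

#' Forward pass of a two-class network
#'
#' Hidden neuron j computes `s(b_j + sum_k w_jk x_k)` with the sigmoid
#' `s(t) = 1 / (1 + exp(-t))`; the output neuron applies the Heaviside
#' function (`h(t) = 1` iff `t >= 0`, a fixed convention) to
#' `b_o + sum_j v_j s_j`. Inputs are the raw triple
#' `(bowley, distance_p, order_p)`.
#'
#' @param net A [cng_network()].
#' @param x Numeric vector of 3 inputs, or an `n x 3` matrix.
#' @return Integer 0/1 vector of classifications.
#' @export
cng_forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  stopifnot(ncol(x) == 3L)
  hidden <- stats::plogis(sweep(x %*% t(net$w), 2L, net$b_h, "+"))
  as.integer(drop(hidden %*% net$v) + net$b_o >= 0)
}

#' Assemble a network training set
#'
#' Three point classes: the positives (positional statistics of candidate
#' pairs), the three fixed negative-control points (order and distance
#' p-values of 1 with Bowley skewness -1, 0, 1), and random points
#' (positional statistics of random CRE pairs; see
#' [random_positional_stats()]). Inputs are fed raw in the order
#' `(bowley, distance_p, order_p)`. A positive coinciding exactly with a
#' negative point is rejected up-front (coverage would be impossible without
#' including a negative).
#'
#' @param positives,randoms Data frames with columns `bowley`, `distance_p`,
#'   `order_p` and optionally an id column (`query` or `id`).
#' @return An object of class `cng_training_set`.
#' @export
cng_training_set <- function(positives, randoms) {
  as_mat <- function(df) {
    m <- as.matrix(df[, c("bowley", "distance_p", "order_p")])
    storage.mode(m) <- "double"
    m
  }
  ids_of <- function(df, prefix) {
    if ("query" %in% names(df)) as.character(df$query)
    else if ("id" %in% names(df)) as.character(df$id)
    else paste0(prefix, seq_len(nrow(df)))
  }
  stopifnot(nrow(positives) >= 1L)
  pos <- as_mat(positives)
  rand <- if (nrow(randoms) > 0L) as_mat(randoms) else matrix(numeric(), 0L, 3L)
  neg <- matrix(c(-1, 1, 1, 0, 1, 1, 1, 1, 1), 3L, 3L, byrow = TRUE)
  colnames(neg) <- c("bowley", "distance_p", "order_p")
  clash <- apply(pos, 1L, function(p) any(apply(neg, 1L, function(q) all(p == q))))
  if (any(clash)) {
    stop(sprintf("%d positive point(s) coincide with a negative-control point", sum(clash)))
  }
  structure(
    list(pos = pos, pos_id = ids_of(positives, "pos"),
         rand = rand, rand_id = ids_of(randoms, "rand"), neg = neg),
    class = "cng_training_set"
  )
}

#' @export
print.cng_training_set <- function(x, ...) {
  cat(sprintf("<cng_training_set> %d positives, %d randoms, 3 negative controls\n",
              nrow(x$pos), nrow(x$rand)))
  invisible(x)
}

# Score a network. Lexicographic order: negative-veto (and, in later cycles,
# zero-uncovered veto) < ratio < size. In cycles after the first the ratio's
# numerator counts not-yet-covered positives only, which is what forces new
# cycles toward new categories.
cng_score <- function(net, ts, uncovered = NULL) {
  pos_in <- cng_forward(net, ts$pos) == 1L
  rand_in <- if (nrow(ts$rand) > 0L) cng_forward(net, ts$rand) == 1L else logical(0)
  neg_in <- cng_forward(net, ts$neg) == 1L
  veto <- any(neg_in)
  n_new <- if (is.null(uncovered)) sum(pos_in) else sum(pos_in & uncovered)
  if (!is.null(uncovered) && n_new == 0L) veto <- TRUE
  ratio <- if (veto) -Inf else n_new / max(sum(rand_in), 1L)
  list(ratio = ratio, size = sum(pos_in) + sum(rand_in), veto = veto,
       pos_in = pos_in, n_rand = sum(rand_in))
}

score_better <- function(a, b) {
  a$ratio > b$ratio || (a$ratio == b$ratio && a$size > b$size)
}

net_to_vec <- function(net) c(as.vector(net$w), net$b_h, net$v, net$b_o)

vec_to_net <- function(vec, n_hidden) {
  structure(
    list(w = matrix(vec[seq_len(3L * n_hidden)], n_hidden, 3L),
         b_h = vec[3L * n_hidden + seq_len(n_hidden)],
         v = vec[4L * n_hidden + seq_len(n_hidden)],
         b_o = vec[5L * n_hidden + 1L]),
    class = "cng_network"
  )
}

#' Mutate or cross networks
#'
#' `"incremental"` shifts exactly one parameter by `+/- step`;
#' `"disruptive"` resamples exactly one parameter from the initialization
#' range; `"crossover"` builds a child by a per-parameter coin flip between
#' two parents. The network structure never changes.
#'
#' @param net Parent network.
#' @param type One of `"incremental"`, `"disruptive"`, `"crossover"`.
#' @param step Incremental step size.
#' @param init_range Disruptive resampling range.
#' @param other Second parent (crossover only).
#' @return A new `cng_network`.
#' @export
cng_mutate <- function(net, type = c("incremental", "disruptive", "crossover"),
                       step = 0.1, init_range = 5, other = NULL) {
  type <- match.arg(type)
  n_hidden <- nrow(net$w)
  vec <- net_to_vec(net)
  if (type == "crossover") {
    stopifnot(!is.null(other))
    vec2 <- net_to_vec(other)
    take <- stats::runif(length(vec)) < 0.5
    vec[take] <- vec2[take]
  } else {
    i <- sample.int(length(vec), 1L)
    if (type == "incremental") {
      vec[i] <- vec[i] + sample(c(-1, 1), 1L) * step
    } else {
      vec[i] <- stats::runif(1L, -init_range, init_range)
    }
  }
  vec_to_net(vec, n_hidden)
}

#' Run one evolutionary cycle
#'
#' Rounds of score-select-mutate over a population until the best score has
#' not improved for `patience` rounds (or `max_rounds` is hit). The best
#' network of a round is always retained, so its score trajectory is
#' non-decreasing.
#'
#' @param ts A [cng_training_set()].
#' @param uncovered Logical vector over positives: which still need covering
#'   (`NULL` in the first cycle: all positives count).
#' @param params [cng_params()].
#' @return List: `net` (best network), `score`, `rounds`.
#' @export
cng_train_cycle <- function(ts, uncovered = NULL, params = cng_params()) {
  p <- params
  # in cycles after the first, fresh networks are constructed to include one
  # of the not-yet-categorized positives: the output bias is raised until a
  # randomly chosen uncovered point classifies as 1
  fresh_net <- function() {
    net <- cng_network(p$n_hidden, p$init_range)
    if (!is.null(uncovered) && any(uncovered)) {
      target <- ts$pos[sample(which(uncovered), 1L), , drop = FALSE]
      z <- drop(stats::plogis(sweep(target %*% t(net$w), 2L, net$b_h, "+")) %*% net$v) +
        net$b_o
      if (z < 0) net$b_o <- net$b_o - z
    }
    net
  }
  pop <- replicate(p$population, fresh_net(), simplify = FALSE)
  best <- NULL
  stagnant <- 0L
  rounds <- 0L
  while (rounds < p$max_rounds) {
    rounds <- rounds + 1L
    scores <- lapply(pop, cng_score, ts = ts, uncovered = uncovered)
    ord <- order(vapply(scores, `[[`, numeric(1), "ratio"),
                 vapply(scores, `[[`, numeric(1), "size"),
                 decreasing = TRUE)
    # keep the best networks, preferring distinct categorizations: clones of
    # one solution would otherwise crowd out the stepping stones the
    # point-crossing score landscape needs
    sig <- vapply(scores, function(s) paste(c(s$pos_in, s$n_rand), collapse = ""),
                  character(1))
    keep <- ord[!duplicated(sig[ord])]
    if (length(keep) < p$top_k) keep <- c(keep, setdiff(ord, keep))
    keep <- keep[seq_len(p$top_k)]
    elite <- pop[keep]
    elite_scores <- scores[keep]
    if (is.null(best) || score_better(elite_scores[[1]], best$score)) {
      best <- list(net = elite[[1]], score = elite_scores[[1]])
      stagnant <- 0L
    } else if (!best$score$veto && best$score$ratio >= 1) {
      # the stagnation clock runs only once an admissible best exists whose
      # category is at least as positive-dense as random-dense (ratio >= 1);
      # below that floor the cycle keeps exploring (bounded by max_rounds)
      stagnant <- stagnant + 1L
    }
    if (stagnant >= p$patience) break
    n_mut <- p$population - p$top_k - p$n_fresh
    mutants <- lapply(seq_len(n_mut), function(i) {
      type <- sample(c("incremental", "disruptive", "crossover"), 1L,
                     prob = c(0.4, 0.3, 0.3))
      parent <- elite[[sample.int(p$top_k, 1L)]]
      other <- if (type == "crossover") elite[[sample.int(p$top_k, 1L)]] else NULL
      cng_mutate(parent, type, step = p$step, init_range = p$init_range,
                 other = other)
    })
    fresh <- replicate(p$n_fresh, fresh_net(), simplify = FALSE)
    pop <- c(elite, mutants, fresh)
  }
  c(best, list(rounds = rounds))
}

#' Train a network ensemble until every positive is categorized
#'
#' Repeats [cng_train_cycle()]; after each cycle the best network's positive
#' members are marked covered, and subsequent cycles score networks by the
#' positives still uncovered (networks covering none are rated lowest).
#' Training ends when every positive is categorized at least once; a cycle
#' cap aborts with a partial ensemble and a warning.
#'
#' @param ts A [cng_training_set()].
#' @param params [cng_params()].
#' @return An object of class `cng_ensemble`: networks, their (all-positive)
#'   member sets, scores, per-cycle metadata, and the coverage map.
#' @export
cng_train <- function(ts, params = cng_params()) {
  n_pos <- nrow(ts$pos)
  covered <- rep(FALSE, n_pos)
  nets <- list(); members <- list(); scores <- list(); cycle_rounds <- integer()
  cycle <- 0L
  while (!all(covered) && cycle < params$max_cycles) {
    cycle <- cycle + 1L
    uncovered <- if (cycle == 1L) NULL else !covered
    res <- cng_train_cycle(ts, uncovered = uncovered, params = params)
    new_pos <- res$score$pos_in & !covered
    if (res$score$veto || !any(new_pos)) {
      # unproductive cycle: try again with a fresh population (max_cycles caps)
      next
    }
    nets[[length(nets) + 1L]] <- res$net
    members[[length(members) + 1L]] <- which(res$score$pos_in)
    scores[[length(scores) + 1L]] <- res$score
    cycle_rounds <- c(cycle_rounds, res$rounds)
    covered <- covered | res$score$pos_in
  }
  if (!all(covered)) {
    warning(sprintf("training ended with partial coverage: %d/%d positives categorized",
                    sum(covered), n_pos))
  }
  structure(
    list(networks = nets, members = members, scores = scores,
         cycle_rounds = cycle_rounds, covered = covered, ts = ts,
         params = params),
    class = "cng_ensemble"
  )
}

#' @export
print.cng_ensemble <- function(x, ...) {
  cat(sprintf("<cng_ensemble> %d network(s); %d/%d positives categorized\n",
              length(x$networks), sum(x$covered), length(x$covered)))
  invisible(x)
}

#' Distance between two network categories
#'
#' `1 - |A intersect B| / min(|A|, |B|)`: 1 means no shared sequences; 0
#' means the smaller category is contained in the larger.
#'
#' @param members_a,members_b Vectors of member identifiers (both non-empty;
#'   otherwise `NA`).
#' @return Value in `[0, 1]`, or `NA`.
#' @export
category_distance <- function(members_a, members_b) {
  if (length(members_a) == 0L || length(members_b) == 0L) return(NA_real_)
  1 - length(intersect(members_a, members_b)) /
    min(length(unique(members_a)), length(unique(members_b)))
}

#' Per-network tables, category-distance matrix and input correlations
#'
#' For each network: its positive members (ids), score components, and the
#' Spearman rank correlations among the three inputs over its members (not
#' computed for networks with a single member); plus the symmetric pairwise
#' category-distance matrix.
#'
#' @param ensemble A [cng_train()] result.
#' @return A list: `networks` (tibble), `members` (named list of id vectors),
#'   `distance_matrix`, `correlations` (tibble with one row per network).
#' @export
ensemble_report <- function(ensemble) {
  n <- length(ensemble$networks)
  ids <- lapply(ensemble$members, function(m) ensemble$ts$pos_id[m])
  nets <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    s <- ensemble$scores[[i]]
    tibble::tibble(network = i, n_members = length(ensemble$members[[i]]),
                   n_random_included = s$n_rand, ratio = s$ratio,
                   size = s$size, rounds = ensemble$cycle_rounds[i])
  }))
  dm <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dm[i, j] <- dm[j, i] <- category_distance(ids[[i]], ids[[j]])
    }
  }
  cors <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    m <- ensemble$ts$pos[ensemble$members[[i]], , drop = FALSE]
    if (nrow(m) < 2L) {
      return(tibble::tibble(network = i, rho_bowley_distance = NA_real_,
                            rho_bowley_order = NA_real_,
                            rho_distance_order = NA_real_))
    }
    sp <- function(a, b) {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b, method = "spearman")
    }
    tibble::tibble(network = i,
                   rho_bowley_distance = sp(m[, 1], m[, 2]),
                   rho_bowley_order = sp(m[, 1], m[, 3]),
                   rho_distance_order = sp(m[, 2], m[, 3]))
  }))
  list(networks = nets, members = stats::setNames(ids, paste0("network_", seq_len(n))),
       distance_matrix = dm, correlations = cors)
}

#' Tidy a trained ensemble
#' @param x A `cng_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per network (members, score components).
#' @export
tidy.cng_ensemble <- function(x, ...) ensemble_report(x)$networks

#' One-row summary of a trained ensemble
#' @inheritParams tidy.cng_ensemble
#' @return One-row tibble: networks, positives, coverage.
#' @export
glance.cng_ensemble <- function(x, ...) {
  tibble::tibble(n_networks = length(x$networks),
                 n_positives = length(x$covered),
                 coverage = mean(x$covered),
                 coverage_complete = all(x$covered))
}

#' Positional statistics of random CRE pairs
#'
#' The random arm of the training set: random CRE pairs (same generator as
#' the background model) evaluated for their actual positional statistics on
#' the promoter set. Pairs with too few co-occurrences, or individually
#' uncomputed statistics, receive the neutral values
#' `(order_p = 1, distance_p = 1, bowley = 0)`.
#'
#' @param promoters A [promoter_set()].
#' @param n_pairs Number of random pairs (default 200).
#' @param len_range Random CRE length range.
#' @param mode Orientation mode.
#' @param index Optional k-mer index.
#' @param iters Null-simulation iterations per pair (default 2000 here; the
#'   random arm needs resolution only near the calibrated center).
#' @return Tibble with `query`, `bowley`, `distance_p`, `order_p`.
#' @export
random_positional_stats <- function(promoters, n_pairs = 200L,
                                    len_range = c(5L, 8L),
                                    mode = c("all", "forward_only"),
                                    index = NULL, iters = 2000L) {
  mode <- match.arg(mode)
  if (is.null(index)) index <- build_kmer_index(promoters, k = min(len_range[1], 8L))
  rows <- lapply(seq_len(n_pairs), function(i) {
    q <- paste(random_cre(len_range[1], len_range[2]),
               random_cre(len_range[1], len_range[2]), sep = ",")
    st <- pair_positional_stats(q, promoters, index = index, mode = mode,
                                iters = iters)
    tibble::tibble(query = q,
                   bowley = ifelse(is.na(st$bowley), 0, st$bowley),
                   distance_p = ifelse(is.na(st$distance_p), 1, st$distance_p),
                   order_p = ifelse(is.na(st$order_p), 1, st$order_p))
  })
  dplyr::bind_rows(rows)
}
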