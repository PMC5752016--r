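# Synthetic promoter sets, expression catalogs, and planted CRE/CRM signals
# with controlled effect sizes. Plants overwrite sequence windows (never
# insert), so the region length and all positional arithmetic stay exact;
# ground-truth manifests make every downstream statistic checkable against
# the construction parameters.

ZT_CATEGORIES <- c("ZT0-ZT4", "ZT4-ZT8", "ZT8-ZT12", "ZT12-ZT16",
                   "ZT16-ZT20", "ZT20-ZT0")
# circadian-style background: peaks before subjective dusk and dawn
ZT_WEIGHTS <- c(0.13, 0.14, 0.26, 0.15, 0.14, 0.18)

#' Generate random promoter sequences
#'
#' @param n Number of promoters.
#' @param region_length Sequence length in bp (default 1000).
#' @param base_probs Probabilities for A, C, G, T.
#' @param prefix Gene-id prefix.
#' @return A [promoter_set()].
#' @export
generate_promoters <- function(n, region_length = 1000L,
                               base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                               prefix = "gene") {
  stopifnot(n >= 1L)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), region_length, replace = TRUE,
                 prob = base_probs), collapse = "")
  }, character(1))
  promoter_set(sprintf("%s%04d", prefix, seq_len(n)), seqs)
}

overwrite_window <- function(seq, start0, piece) {
  # start0 is 0-based; overwrite keeps length fixed
  paste0(substr(seq, 1L, start0), piece,
         substr(seq, start0 + nchar(piece) + 1L, nchar(seq)))
}

# Draw placements for one promoter under the position model. Returns a list
# of per-member 0-based starts (ordered as members) or NULL when no valid
# placement was found in `tries` attempts.
draw_placement <- function(members, L, position, order_bias) {
  w <- nchar(members)
  type <- position$type
  for (try in seq_len(200L)) {
    if (length(members) == 1L) {
      if (type == "tss_proximal") {
        dmax <- position$dmax %||% 300
        pow <- position$power %||% 3
        dtss <- round(dmax * stats::runif(1L)^pow)
        s <- L - dtss - w[1]
        if (s < 0L) next
        return(list(starts = as.integer(s)))
      }
      return(list(starts = sample.int(L - w[1] + 1L, 1L) - 1L))
    }
    # pairs: choose which member sits TSS-proximal
    a_prox <- stats::runif(1L) < order_bias
    iw <- if (a_prox) c(1L, 2L) else c(2L, 1L)   # proximal, distal member index
    wp <- w[iw[1]]; wd <- w[iw[2]]
    if (type == "fixed_spacing") {
      d <- position$spacing + if ((position$jitter %||% 0) > 0)
        sample(-position$jitter:position$jitter, 1L) else 0L
      dtss_p <- sample(0:(L - wd - d), 1L)
    } else if (type == "tss_proximal") {
      dmax <- position$dmax %||% 300
      pow <- position$power %||% 3
      dtss_p <- round(dmax * stats::runif(1L)^pow)
      # spacing from the |U - V| null itself: F(d) = 1 - (1 - d/L)^2
      d <- round(L * (1 - sqrt(stats::runif(1L))))
    } else { # uniform: independent positions
      sa <- sample(0:(L - w[1]), 1L)
      sb <- sample(0:(L - w[2]), 1L)
      if (sa <= sb && sa + w[1] > sb) next
      if (sb <= sa && sb + w[2] > sa) next
      return(list(starts = as.integer(c(sa, sb))))
    }
    if (d < wp) next                       # members must not overlap
    if (dtss_p + d + wd > L) next          # distal member must fit
    sp <- L - dtss_p - wp
    sd_ <- L - dtss_p - d - wd
    starts <- integer(2L)
    starts[iw] <- as.integer(c(sp, sd_))
    return(list(starts = starts))
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant a CRE or CRE pair into a promoter set
#'
#' Overwrites sequence windows of randomly chosen target promoters according
#' to a position model and returns the modified set with the exact planted
#' coordinates.
#'
#' Position models: `list(type = "uniform")` (independent uniform positions);
#' `list(type = "tss_proximal", dmax, power)` (TSS distance of the proximal
#' edge drawn as `dmax * U^power`, pair spacing drawn from the `|U - V|`
#' spacing null so that no artificial distance preference is introduced);
#' `list(type = "fixed_spacing", spacing, jitter)`.
#'
#' @param promoters A [promoter_set()].
#' @param members Character vector of 1 or 2 concrete motifs.
#' @param n_target Number of promoters to plant (sampled without
#'   replacement), or a character vector of gene ids.
#' @param position Position model (see above; default uniform).
#' @param order_bias For pairs: probability that the *first* member is
#'   TSS-proximal (`0.5` to `1`).
#' @return A list: `promoters` (modified set), `manifest` (tibble with
#'   planted coordinates: per gene, member starts, edge spacing, module TSS
#'   distance, proximal member).
#' @export
plant_motifs <- function(promoters, members, n_target,
                         position = list(type = "uniform"), order_bias = 0.5) {
  members <- toupper(members)
  stopifnot(length(members) %in% 1:2,
            !any(stringi::stri_detect_regex(members, "[^ACGT]")),
            order_bias >= 0.5, order_bias <= 1)
  L <- region_length(promoters)
  targets <- if (is.character(n_target)) n_target
             else sample(promoters$gene_id, n_target)
  seqs <- stats::setNames(promoters$sequence, promoters$gene_id)
  rows <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    g <- targets[i]
    pl <- draw_placement(members, L, position, order_bias)
    if (is.null(pl)) stop("could not place the motif(s) within the position model constraints")
    s <- pl$starts
    for (j in seq_along(members)) {
      seqs[[g]] <- overwrite_window(seqs[[g]], s[j], members[j])
    }
    dtss <- L - (s + nchar(members))
    rows[[i]] <- tibble::tibble(
      gene_id = g,
      start_a = s[1],
      start_b = if (length(members) == 2L) s[2] else NA_integer_,
      spacing = if (length(members) == 2L) abs(dtss[1] - dtss[2]) else NA_integer_,
      crm_dist_tss = min(dtss),
      proximal = if (length(members) == 2L) c("a", "b")[which.min(dtss)] else NA_character_
    )
  }
  list(promoters = promoter_set(promoters$gene_id, unname(seqs[promoters$gene_id])),
       manifest = dplyr::bind_rows(rows))
}

#' Generate an expression catalog with optional planted enrichment
#'
#' Unplanted genes draw their category from the background weights; planted
#' genes receive the target category with probability `rho` and otherwise
#' draw from the remaining categories with renormalized background weights,
#' so `rho` is the exact target-category probability (`rho` equal to the
#' target's background weight reproduces the background).
#'
#' @param gene_ids Character vector of gene ids.
#' @param categories Ordered category labels (default the six ZT bins).
#' @param weights Background category weights (default circadian-style).
#' @param planted Gene ids of the planted set (default none).
#' @param target_category Enriched category for planted genes.
#' @param rho Target-category probability for planted genes.
#' @return An [expression_catalog()].
#' @export
generate_catalog <- function(gene_ids, categories = ZT_CATEGORIES,
                             weights = ZT_WEIGHTS, planted = character(),
                             target_category = NULL, rho = NULL) {
  weights <- weights / sum(weights)
  stopifnot(length(weights) == length(categories))
  cats <- sample(categories, length(gene_ids), replace = TRUE, prob = weights)
  names(cats) <- gene_ids
  if (length(planted) > 0L) {
    stopifnot(!is.null(target_category), target_category %in% categories,
              !is.null(rho), rho >= 1 / length(categories), rho <= 1)
    others <- setdiff(categories, target_category)
    w_o <- weights[match(others, categories)]
    for (g in planted) {
      cats[[g]] <- if (stats::runif(1L) < rho) target_category
                   else sample(others, 1L, prob = w_o / sum(w_o))
    }
  }
  expression_catalog(gene_ids, unname(cats[gene_ids]), categories = categories)
}

two_cluster_training_data <- function() {
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  mk <- function(n, center, sd, cluster) {
    tibble::tibble(
      id = sprintf("%s_%02d", cluster, seq_len(n)),
      cluster = cluster,
      bowley = clip(stats::rnorm(n, center[1], sd), -1, 1),
      distance_p = clip(stats::rnorm(n, center[2], sd), 1e-6, 1),
      order_p = clip(stats::rnorm(n, center[3], sd / 10), 1e-6, 1)
    )
  }
  # both clusters sit well away from the negative-control points
  # (p-values of 1 with skewness -1/0/1), so admissible categories around
  # either cluster are reachable by the evolver
  positives <- dplyr::bind_rows(
    mk(16L, c(-0.60, 0.35, 0.020), 0.03, "cluster_a"),
    mk(8L, c(0.55, 0.85, 0.450), 0.03, "cluster_b")
  )
  # every cluster lies strictly interior to the random cloud's support in
  # each coordinate: a loose category reaching from one cluster toward the
  # other necessarily sweeps up random points and scores below a tight single-cluster
  # category, which is what drives the ensemble toward one network per
  # cluster
  randoms <- tibble::tibble(
    id = sprintf("rand_%02d", seq_len(80L)),
    bowley = stats::runif(80L, -0.75, 0.75),
    distance_p = stats::runif(80L, 0.25, 0.95),
    order_p = stats::runif(80L, 0.005, 0.60)
  )
  list(positives = positives, randoms = randoms)
}

#' Standard synthetic fixtures
#'
#' A deterministic bundle of the study fixtures used throughout the tests and
#' the calibration runs, generated from one seed:
#'
#' * `null`: 100 promoters x 1000 bp, circadian-style catalog, no plants.
#' * `single_cre`: the evening element `AAAATATCT` planted in 30 of 100
#'   promoters at uniform positions, with 90% of planted genes in
#'   `ZT8-ZT12`.
#' * `pair_order`: the pair `CCACGTGGC,ACAGTACT` planted in 60 of 200
#'   promoters; TSS-proximal module positions (`300 U^3` bp from the TSS),
#'   spacing drawn from the spacing null, first member TSS-proximal with
#'   probability 0.95; 90% of planted genes in `ZT4-ZT8`.
#' * `pair_spacing`: the same pair at fixed 50 bp spacing, unbiased order,
#'   90% of planted genes in `ZT12-ZT16`.
#' * `two_cluster`: a network-training fixture with two well-separated
#'   positive clusters (16 + 8 points) and 40 random points filling the space
#'   between them.
#'
#' @param seed Integer seed; the bundle is byte-reproducible given the seed.
#' @return Named list of fixtures. Sequence fixtures carry `promoters`,
#'   `catalog`, `manifest`, `meta`; `two_cluster` carries `positives`,
#'   `randoms`, `meta`.
#' @export
standard_fixtures <- function(seed = 1L) {
  set.seed(seed)
  fixtures <- list()

  proms <- generate_promoters(100L)
  fixtures$null <- list(
    promoters = proms,
    catalog = generate_catalog(proms$gene_id),
    manifest = NULL,
    meta = list(name = "null", query = NULL)
  )

  proms <- generate_promoters(100L)
  pl <- plant_motifs(proms, "AAAATATCT", 30L, position = list(type = "uniform"))
  fixtures$single_cre <- list(
    promoters = pl$promoters,
    catalog = generate_catalog(proms$gene_id, planted = pl$manifest$gene_id,
                               target_category = "ZT8-ZT12", rho = 0.9),
    manifest = pl$manifest,
    meta = list(name = "single_cre", query = "AAAATATCT",
                target_category = "ZT8-ZT12", rho = 0.9, n_planted = 30L)
  )

  proms <- generate_promoters(200L)
  pl <- plant_motifs(proms, c("CCACGTGGC", "ACAGTACT"), 60L,
                     position = list(type = "tss_proximal", dmax = 300, power = 3),
                     order_bias = 0.95)
  fixtures$pair_order <- list(
    promoters = pl$promoters,
    catalog = generate_catalog(proms$gene_id, planted = pl$manifest$gene_id,
                               target_category = "ZT4-ZT8", rho = 0.9),
    manifest = pl$manifest,
    meta = list(name = "pair_order", query = "CCACGTGGC,ACAGTACT",
                target_category = "ZT4-ZT8", rho = 0.9, n_planted = 60L,
                order_bias = 0.95)
  )

  proms <- generate_promoters(200L)
  pl <- plant_motifs(proms, c("CCACGTGGC", "ACAGTACT"), 60L,
                     position = list(type = "fixed_spacing", spacing = 50L, jitter = 0L),
                     order_bias = 0.5)
  fixtures$pair_spacing <- list(
    promoters = pl$promoters,
    catalog = generate_catalog(proms$gene_id, planted = pl$manifest$gene_id,
                               target_category = "ZT12-ZT16", rho = 0.9),
    manifest = pl$manifest,
    meta = list(name = "pair_spacing", query = "CCACGTGGC,ACAGTACT",
                target_category = "ZT12-ZT16", rho = 0.9, n_planted = 60L,
                spacing = 50L)
  )

  tc <- two_cluster_training_data()
  fixtures$two_cluster <- c(tc, list(meta = list(name = "two_cluster",
                                                 n_clusters = 2L)))
  fixtures
}

#' Write a sequence fixture to disk
#'
#' Emits standard files — `promoters.fasta`, `catalog.tsv`, and (when plants
#' exist) `manifest.tsv` — so fixtures are indistinguishable from real
#' inputs.
#'
#' @param fixture One element of [standard_fixtures()] carrying promoters.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_promoters(fixture$promoters, file.path(dir, "promoters.fasta"))
  write_catalog(fixture$catalog, file.path(dir, "catalog.tsv"))
  if (!is.null(fixture$manifest)) {
    utils::write.table(fixture$manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
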