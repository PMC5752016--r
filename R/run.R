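# File-based run drivers: a run configuration, the single-query screen, the
# exhaustive pair sweep, and network training, each writing a plain-text
# output bundle (TSV + gene lists + config echo + log; no timestamps, so
# identical configurations and seeds yield byte-identical outputs).

#' Assemble a run configuration
#'
#' @param ... Named settings. Recognized keys: `promoters` (FASTA path or
#'   `promoter_set`), `catalog` (TSV path or `expression_catalog`), `queries`
#'   (text path or character vector), `threshold_sd`, `min_matches`,
#'   `n_random`, `n_backgrounds`, `len_range`, `mode`, `iters`
#'   (distance-null iterations), `positional` (compute positional stats for
#'   candidate pairs), `seed`, `out` (output directory), and for the network
#'   step `positional_tsv`, `randoms_tsv`, `n_random_pairs`, `cng`
#'   (overrides for [cng_params()]).
#' @return A list of class `run_config` with defaults filled in.
#' @export
run_config <- function(...) {
  cfg <- list(threshold_sd = 1, min_matches = 20L, n_random = 100L,
              n_backgrounds = 100L, len_range = c(5L, 8L), mode = "all",
              iters = 10000L, positional = TRUE, n_random_pairs = 200L,
              seed = 1L, out = NULL)
  o <- list(...)
  cfg[names(o)] <- o
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

load_promoters <- function(x) if (inherits(x, "promoter_set")) x else read_promoters(x)
load_catalog <- function(x) if (inherits(x, "expression_catalog")) x else read_catalog(x)
load_queries <- function(x) {
  if (length(x) == 1L && file.exists(x)) read_query_file(x) else as.character(x)
}

sanitize_query <- function(q) gsub("[^A-Za-z0-9]+", "_", q)

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

echo_config <- function(config, dir, log_lines) {
  cfg <- unclass(config)
  cfg$promoters <- if (is.character(cfg$promoters)) cfg$promoters else "<in-memory promoter_set>"
  cfg$catalog <- if (is.character(cfg$catalog)) cfg$catalog else "<in-memory catalog>"
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  writeLines(log_lines, file.path(dir, "run.log"))
}

#' Run the full screen on a query set
#'
#' Reads inputs, builds the seeded background model, evaluates every query,
#' computes positional statistics for candidate pairs, and writes
#' `candidates.tsv`, `dem.tsv`, `positional.tsv`, per-query matched gene
#' lists under `matched_genes/`, the configuration echo, and a run log.
#'
#' @param config A [run_config()] with `promoters`, `catalog`, `queries`,
#'   `seed`, and `out` set.
#' @return Invisibly, a list with the result tables and output paths.
#' @export
run_edcc <- function(config) {
  stopifnot(inherits(config, "run_config"), !is.null(config$out))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  promoters <- load_promoters(config$promoters)
  catalog <- load_catalog(config$catalog)
  queries <- load_queries(config$queries)
  index <- build_kmer_index(promoters, k = min(config$len_range[1], 8L))
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("promoters: %d x %d bp", nrow(promoters), region_length(promoters)),
                 sprintf("catalog: %d genes, %d categories", nrow(catalog),
                         nlevels(catalog$category)),
                 sprintf("queries: %d", length(queries)))
  if (length(queries) == 0L) {
    warning("empty query set: writing empty outputs")
    write_tsv_file(tibble::tibble(query = character()), file.path(config$out, "candidates.tsv"))
    echo_config(config, config$out, c(log_lines, "empty query set"))
    return(invisible(list(candidates = tibble::tibble(), out = config$out)))
  }
  model <- build_background_model(promoters, catalog,
                                  n_random = config$n_random,
                                  n_backgrounds = config$n_backgrounds,
                                  len_range = config$len_range,
                                  mode = config$mode, index = index)
  log_lines <- c(log_lines, sprintf("background rejected draws: %d", model$n_rejected))
  calls <- lapply(queries, function(q) {
    evaluate_query(q, promoters, catalog, model,
                   threshold_sd = config$threshold_sd,
                   min_matches = config$min_matches,
                   mode = config$mode, index = index)
  })
  candidates <- dplyr::bind_rows(lapply(calls, glance))
  dems <- dplyr::bind_rows(lapply(calls, function(cl) {
    d <- tidy(cl)
    if (nrow(d) > 0L) d$query <- cl$query
    d
  }))
  positional <- tibble::tibble(query = character(), n_promoters = integer(),
                               n_ordered = integer(), order_p = double(),
                               distance_p = double(), bowley = double())
  if (isTRUE(config$positional)) {
    cand_pairs <- candidates$query[candidates$candidate &
                                     grepl(",", candidates$query, fixed = TRUE)]
    if (length(cand_pairs) > 0L) {
      positional <- dplyr::bind_rows(lapply(cand_pairs, function(q) {
        pair_positional_stats(q, promoters, index = index, mode = config$mode,
                              iters = config$iters)
      }))
    }
  }
  gene_dir <- file.path(config$out, "matched_genes")
  dir.create(gene_dir, showWarnings = FALSE)
  for (cl in calls) {
    genes <- matched_genes(cl$query, promoters, index = index, mode = config$mode)
    writeLines(genes, file.path(gene_dir, paste0(sanitize_query(cl$query), ".txt")))
  }
  write_tsv_file(candidates, file.path(config$out, "candidates.tsv"))
  write_tsv_file(dems, file.path(config$out, "dem.tsv"))
  write_tsv_file(positional, file.path(config$out, "positional.tsv"))
  echo_config(config, config$out, log_lines)
  invisible(list(candidates = candidates, dems = dems, positional = positional,
                 model = model, out = config$out))
}

#' Sweep all unordered pairs of a motif list
#'
#' Enumerates the `m (m + 1) / 2` unordered pairs (homotypic included) of the
#' deduplicated motif list and streams their evaluation against one seeded
#' background model, flushing results every `flush_every` pairs so an
#' interrupted sweep resumes at the first unevaluated pair with identical
#' final output.
#'
#' @param config A [run_config()].
#' @param motifs Character vector of motifs (or path to a motif list).
#' @param count_only If `TRUE`, return the pair count without evaluating.
#' @param flush_every Flush interval (default 1000).
#' @return The pair count (`count_only`), else invisibly the result tibble.
#' @export
run_pairs <- function(config, motifs, count_only = FALSE, flush_every = 1000L) {
  motifs <- load_queries(motifs)
  if (count_only) return(count_pairs(motifs))
  stopifnot(inherits(config, "run_config"), !is.null(config$out))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  pairs <- enumerate_pairs(motifs)
  out_path <- file.path(config$out, "pair_candidates.tsv")
  done <- 0L
  if (file.exists(out_path)) {
    done <- length(readLines(out_path)) - 1L
    if (done >= nrow(pairs)) return(invisible(utils::read.delim(out_path)))
  }
  set.seed(config$seed)
  promoters <- load_promoters(config$promoters)
  catalog <- load_catalog(config$catalog)
  index <- build_kmer_index(promoters, k = min(config$len_range[1], 8L))
  model <- build_background_model(promoters, catalog,
                                  n_random = config$n_random,
                                  n_backgrounds = config$n_backgrounds,
                                  len_range = config$len_range,
                                  mode = config$mode, index = index)
  # member gene sets are cached: each motif is matched once
  cache <- new.env(parent = emptyenv())
  genes_of <- function(m) {
    if (is.null(cache[[m]])) {
      cache[[m]] <- unique(find_matches(m, promoters, index = index,
                                        mode = config$mode)$gene_id)
    }
    cache[[m]]
  }
  if (done == 0L) {
    writeLines(paste(c("query", "n_matches", "candidate", "votes", "flagged"),
                     collapse = "\t"), out_path)
  }
  con <- file(out_path, open = "a")
  on.exit(close(con), add = TRUE)
  buf <- character(0)
  for (i in seq_len(nrow(pairs))) {
    if (i <= done) next
    genes <- intersect(genes_of(pairs$a[i]), genes_of(pairs$b[i]))
    cl <- evaluate_gene_set(pairs$query[i], genes, catalog, model,
                            threshold_sd = config$threshold_sd,
                            min_matches = config$min_matches)
    buf <- c(buf, paste(c(cl$query, cl$n_matches, cl$candidate, cl$votes,
                          paste(cl$flagged_categories, collapse = ",")),
                        collapse = "\t"))
    if (length(buf) >= flush_every) {
      writeLines(buf, con); flush(con); buf <- character(0)
    }
  }
  if (length(buf) > 0L) writeLines(buf, con)
  flush(con)
  invisible(utils::read.delim(out_path))
}

#' Train a network ensemble from a positional-statistics table
#'
#' Positives are read from `config$positional_tsv` (or passed as a data
#' frame via `config$positional_table`); the random arm comes from
#' `config$randoms_tsv` when given, otherwise `config$n_random_pairs` random
#' CRE pairs are evaluated on the promoter set. Writes per-network
#' descriptions and member lists, the category-distance matrix, and a
#' combined report.
#'
#' @param config A [run_config()] with `seed`, `out`, and a positional
#'   source.
#' @return Invisibly, a list with the trained ensemble and its report.
#' @export
run_cng <- function(config) {
  stopifnot(inherits(config, "run_config"), !is.null(config$out))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  positives <- if (!is.null(config$positional_table)) config$positional_table
               else utils::read.delim(config$positional_tsv)
  positives <- positives[stats::complete.cases(
    positives[, c("bowley", "distance_p", "order_p")]), ]
  if (nrow(positives) == 0L) stop("no usable positive rows in the positional table")
  randoms <- if (!is.null(config$randoms_tsv)) {
    utils::read.delim(config$randoms_tsv)
  } else {
    promoters <- load_promoters(config$promoters)
    random_positional_stats(promoters, n_pairs = config$n_random_pairs,
                            len_range = config$len_range, mode = config$mode)
  }
  params <- do.call(cng_params, config$cng %||% list())
  ts <- cng_training_set(positives, randoms)
  ens <- cng_train(ts, params = params)
  rep <- ensemble_report(ens)
  net_dir <- file.path(config$out, "networks")
  mem_dir <- file.path(config$out, "members")
  dir.create(net_dir, showWarnings = FALSE)
  dir.create(mem_dir, showWarnings = FALSE)
  for (i in seq_along(ens$networks)) {
    net <- ens$networks[[i]]
    jsonlite::write_json(
      list(n_hidden = nrow(net$w), hidden_weights = net$w,
           hidden_biases = net$b_h, output_weights = net$v,
           output_bias = net$b_o),
      file.path(net_dir, sprintf("network_%02d.json", i)),
      digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
    writeLines(rep$members[[i]], file.path(mem_dir, sprintf("network_%02d.txt", i)))
  }
  dm <- as.data.frame(rep$distance_matrix)
  names(dm) <- paste0("network_", seq_len(ncol(dm)))
  write_tsv_file(cbind(network = paste0("network_", seq_len(nrow(dm))), dm),
                 file.path(config$out, "distance_matrix.tsv"))
  write_tsv_file(dplyr::left_join(rep$networks, rep$correlations, by = "network"),
                 file.path(config$out, "report.tsv"))
  echo_config(config, config$out,
              c(sprintf("seed: %d", config$seed),
                sprintf("positives: %d, randoms: %d", nrow(positives), nrow(randoms)),
                sprintf("networks: %d, coverage %d/%d", length(ens$networks),
                        sum(ens$covered), length(ens$covered))))
  invisible(list(ensemble = ens, report = rep, out = config$out))
}
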