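test_that("the screen driver writes a complete, reusable output bundle", {
  fx <- get_fixtures()$single_cre
  out <- withr::local_tempdir()
  cfg <- run_config(promoters = fx$promoters, catalog = fx$catalog,
                    queries = c(fx$meta$query, "CCCCCGGGGGAA"),
                    n_random = 30, n_backgrounds = 20, seed = 41, out = out)
  res <- run_edcc(cfg)
  expect_true(all(file.exists(file.path(out, c("candidates.tsv", "dem.tsv",
                                               "positional.tsv", "config.yaml",
                                               "run.log")))))
  cand <- utils::read.delim(file.path(out, "candidates.tsv"))
  expect_true(cand$candidate[cand$query == fx$meta$query])
  genes <- readLines(file.path(out, "matched_genes", "AAAATATCT.txt"))
  expect_true(all(fx$manifest$gene_id %in% genes))
  dems <- utils::read.delim(file.path(out, "dem.tsv"))
  # the sparse second query has no cataloged matches, hence no DEM rows
  expect_identical(nrow(dems), 6L)
  expect_true(all(dems$query == fx$meta$query))
})

test_that("an empty query set warns and still succeeds", {
  fx <- get_fixtures()$null
  out <- withr::local_tempdir()
  cfg <- run_config(promoters = fx$promoters, catalog = fx$catalog,
                    queries = character(0), seed = 42, out = out)
  expect_warning(run_edcc(cfg), "empty")
  expect_true(file.exists(file.path(out, "candidates.tsv")))
})

test_that("pair sweeps count, stream, and resume identically", {
  motifs <- c("AAAAA", "CCCCC", "GGGGG", "TTTTT", "ACACA",
              "GTGTG", "AATTC", "CGCGA", "TTAAG", "GCCGT")
  expect_identical(run_pairs(run_config(), motifs, count_only = TRUE), 55)

  fx <- get_fixtures()$null
  small <- motifs[1:5]   # 15 pairs
  base <- run_config(promoters = fx$promoters, catalog = fx$catalog,
                     n_random = 15, n_backgrounds = 10, min_matches = 5, seed = 43)
  out1 <- withr::local_tempdir()
  base$out <- out1
  run_pairs(base, small, flush_every = 4)
  full <- readLines(file.path(out1, "pair_candidates.tsv"))
  expect_identical(length(full), 16L)   # header + 15 pairs

  # interrupt after 7 pairs, then resume: byte-identical final table
  out2 <- withr::local_tempdir()
  base$out <- out2
  writeLines(full[1:8], file.path(out2, "pair_candidates.tsv"))
  run_pairs(base, small, flush_every = 4)
  expect_identical(readLines(file.path(out2, "pair_candidates.tsv")), full)
})

test_that("network training driver emits networks, members and reports", {
  tc <- get_fixtures()$two_cluster
  out <- withr::local_tempdir()
  rnd <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tc$randoms, rnd, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- run_config(positional_table = tc$positives, randoms_tsv = rnd,
                    seed = 44, out = out)
  res <- run_cng(cfg)
  n <- length(res$ensemble$networks)
  expect_gte(n, 2L)
  expect_true(all(res$ensemble$covered))
  expect_true(all(file.exists(file.path(out, "networks",
                                        sprintf("network_%02d.json", seq_len(n))))))
  expect_true(file.exists(file.path(out, "distance_matrix.tsv")))
  rep_tab <- utils::read.delim(file.path(out, "report.tsv"))
  expect_identical(nrow(rep_tab), n)
  # serialized networks reload to the same forward behaviour
  js <- jsonlite::read_json(file.path(out, "networks", "network_01.json"),
                            simplifyVector = TRUE)
  net <- structure(list(w = matrix(unlist(js$hidden_weights), js$n_hidden, 3,
                                   byrow = TRUE),
                        b_h = js$hidden_biases, v = js$output_weights,
                        b_o = js$output_bias), class = "cng_network")
  x <- as.matrix(tc$positives[, c("bowley", "distance_p", "order_p")])
  expect_identical(cng_forward(net, x),
                   cng_forward(res$ensemble$networks[[1]], x))
})

test_that("yaml configurations round-trip", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(threshold_sd = 2, min_matches = 10, seed = 7,
                        mode = "forward_only"), tmp)
  cfg <- read_run_config(tmp)
  expect_equal(cfg$threshold_sd, 2)
  expect_equal(cfg$min_matches, 10)
  expect_identical(cfg$mode, "forward_only")
  expect_identical(cfg$n_backgrounds, 100L)   # defaults preserved
})

test_that("plots build without errors", {
  fx <- get_fixtures()$single_cre
  model <- get_model("single_cre")
  call <- evaluate_query(fx$meta$query, fx$promoters, fx$catalog, model,
                         index = get_index("single_cre"))
  expect_s3_class(autoplot(call), "ggplot")
  tc <- get_fixtures()$two_cluster
  ts <- cng_training_set(tc$positives, tc$randoms)
  set.seed(45)
  ens <- cng_train(ts)
  expect_s3_class(autoplot(ens), "ggplot")
})
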