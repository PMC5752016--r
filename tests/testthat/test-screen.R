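test_that("random CREs respect length bounds, composition and determinism", {
  set.seed(7)
  lens <- replicate(200, nchar(random_cre()))
  expect_true(all(lens %in% 5:8))
  set.seed(123); a <- random_cre()
  set.seed(123); b <- random_cre()
  expect_identical(a, b)
  set.seed(8)
  bases <- strsplit(paste(replicate(2000, random_cre(5, 8)), collapse = ""), "")[[1]]
  freq <- table(bases) / length(bases)
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("background model: positive sds on the circadian-style fixture, degenerate catalog collapses", {
  model <- get_model("null")
  expect_true(all(model$sd > 0))
  expect_equal(rowSums(model$mean), rep(100, model$n_backgrounds))
  # mean of random DEMs tracks the catalog background (resampling property)
  bg <- model$background$pct
  mean_dev <- abs(colMeans(model$mean) - bg)
  expect_true(all(mean_dev < 2 * colMeans(model$sd) / sqrt(model$n_random)))

  # all genes in one category: every random DEM is [100, 0, ...], sd 0
  fx <- get_fixtures()$null
  degenerate <- expression_catalog(fx$promoters$gene_id,
                                   rep("only", nrow(fx$promoters)),
                                   categories = c("only", "other"))
  set.seed(9)
  m0 <- build_background_model(fx$promoters, degenerate, n_random = 10,
                               n_backgrounds = 3, index = get_index("null"))
  expect_true(all(m0$sd == 0))
  expect_true(all(m0$mean[, 1] == 100))
})

test_that("candidate calls: planted signal flagged, ubiquitous motif is not, sparse motif is insufficient", {
  fx <- get_fixtures()$single_cre
  model <- get_model("single_cre")
  call <- evaluate_query(fx$meta$query, fx$promoters, fx$catalog, model,
                         index = get_index("single_cre"))
  expect_true(call$candidate)
  expect_gt(call$votes, model$n_backgrounds / 2)
  expect_true(fx$meta$target_category %in% call$flagged_categories)
  expect_gte(call$n_matches, fx$meta$n_planted)

  # a motif present in every promoter reproduces the background exactly
  ubiquitous <- evaluate_query("A", fx$promoters, fx$catalog, model,
                               index = get_index("single_cre"))
  expect_identical(ubiquitous$n_matches, nrow(fx$promoters))
  expect_false(ubiquitous$candidate)
  expect_identical(ubiquitous$votes, 0L)

  # a motif in fewer promoters than min_matches is refused with a reason
  rare <- substr(fx$promoters$sequence[1], 101, 112)   # present, but rare
  sparse <- evaluate_query(rare, fx$promoters, fx$catalog, model,
                           min_matches = 20, index = get_index("single_cre"))
  expect_gte(sparse$n_matches, 1L)
  expect_lt(sparse$n_matches, 20L)
  expect_false(sparse$candidate)
  expect_identical(sparse$reason, "insufficient occurrences")

  g <- glance(call)
  expect_identical(g$candidate, TRUE)
  expect_identical(nrow(tidy(call)), 6L)
})

test_that("zero-sd categories flag only genuine deviations", {
  expect_identical(crmscan:::sd_ratio(c(0, 5), c(0, 0)), c(0, Inf))
  expect_identical(crmscan:::sd_ratio(c(2, 4), c(1, 2)), c(2, 2))
})

test_that("quartile dispersion uses linearly interpolated quartiles", {
  counts <- c(180, 182, 184, 186, 188)
  expect_equal(quartile_dispersion(counts), (186 - 182) / (186 + 182))
  expect_identical(quartile_dispersion(5), NA_real_)
  expect_equal(quartile_dispersion(rep(7, 5)), 0)
})

test_that("repeated screens are seed-deterministic and report overlap and dispersion", {
  fx <- get_fixtures()$null
  queries <- c("AAAAA", "CCGGT", "TTTTTTA")
  run_once <- function() {
    set.seed(55)
    run_query_set(queries, fx$promoters, fx$catalog, n_repeats = 2,
                  n_random = 20, n_backgrounds = 10, index = get_index("null"))
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$results, r2$results)
  expect_true(r1$overlap >= 0 && r1$overlap <= 1)
  expect_identical(nrow(glance(r1)), 1L)
  expect_identical(nrow(tidy(r1)), length(queries))
  set.seed(56)
  single <- run_query_set(queries[1], fx$promoters, fx$catalog, n_repeats = 1,
                          n_random = 10, n_backgrounds = 5, index = get_index("null"))
  expect_identical(single$qdc, NA_real_)
})

test_that("pair enumeration is complete, deduplicated and lexicographic", {
  expect_identical(nrow(enumerate_pairs("ACGT")), 1L)
  p4 <- enumerate_pairs(c("TT", "AA", "CC", "GG", "aa"))
  expect_identical(nrow(p4), 10L)
  expect_true(all(p4$a <= p4$b))
  expect_identical(p4$query[1], "AA,AA")
  expect_identical(count_pairs(sprintf("m%04d", 1:1755)), 1540890)
})
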