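mk_matches <- function(gene_id, dist_tss, width = 5L, L = 1000L) {
  tibble::tibble(gene_id = gene_id,
                 start = L - dist_tss - width,
                 variant = strrep("A", width), orientation = "forward",
                 width = width, dist_tss = as.integer(dist_tss))
}

test_that("placements record closest spacing, module position and order", {
  a <- mk_matches("g1", 100)
  b <- mk_matches("g1", 300)
  pl <- observed_placements(a, b)
  expect_identical(pl$distance, 200L)
  expect_identical(pl$crm_dist_tss, 100L)
  expect_identical(pl$proximal, "a")

  # ties on TSS distance drop the promoter from the order test only
  tie <- observed_placements(mk_matches("g1", 50), mk_matches("g1", 50))
  expect_identical(tie$proximal, NA_character_)
  expect_identical(tie$distance, 0L)

  # closest occurrence pair wins
  multi <- observed_placements(mk_matches(c("g1", "g1"), c(50, 400)),
                               mk_matches("g1", 60))
  expect_identical(multi$distance, 10L)
  expect_identical(multi$crm_dist_tss, 50L)

  none <- observed_placements(mk_matches("g1", 10), mk_matches("g2", 10))
  expect_identical(nrow(none), 0L)
})

test_that("stochastic spacing null has the closed-form mean and bounds", {
  set.seed(10)
  nd <- null_distance_distribution(1, 1, region_length = 1000, iters = 10000)
  expect_length(nd, 10000L)
  expect_true(all(nd >= 0 & nd < 1000))
  expect_lt(abs(mean(nd) - 1000 / 3), 10)   # E|U - V| = L / 3
  set.seed(11); x <- null_distance_distribution(2.4, 0.2, iters = 50)
  set.seed(11); y <- null_distance_distribution(2.4, 0.2, iters = 50)
  expect_identical(x, y)
  # rates below 1 are floored at one occurrence per member
  expect_true(all(null_distance_distribution(0.01, 0.01, iters = 100) >= 0))
})

test_that("distance test behaves at the extremes and refuses tiny samples", {
  set.seed(12)
  nd <- null_distance_distribution(1, 1, iters = 5000)
  expect_equal(distance_test(nd, nd), 1)
  expect_lt(distance_test(rep(10, 30), nd), 1e-4)
  expect_identical(distance_test(c(5, 7), nd), NA_real_)
  expect_error(distance_test(1:10, rep(3, 100)), "degenerate")
})

test_that("order test equals the exact enumeration oracle", {
  for (n in 1:12) {
    for (x in seq.int(ceiling(n / 2), n)) {
      expect_equal(order_test(n, x), order_test_oracle(n, x), tolerance = 1e-12)
    }
  }
  expect_identical(order_test(1, 1), 1)
  expect_equal(order_test(10, 10), 2 * 0.5^10)
  # the printed value for the 34-promoter pair: 3.86e-5 to 3 significant figures
  expect_equal(order_test(34, 29), 662424 / 2^34, tolerance = 1e-12)
  expect_equal(signif(order_test(34, 29), 3), 3.86e-5)
  expect_identical(order_test(0, 0), NA_real_)
  expect_error(order_test(10, 2), "more frequent")
})

test_that("Bowley skewness is bounded, symmetric at zero, and reflects sign", {
  expect_equal(bowley_skewness(c(1, 2, 3, 4, 5)), 0)
  # Q1 = 100, Q2 = 200, Q3 = 500 -> 0.5
  positions <- c(100, 100, 100, 200, 500, 500, 500)
  q <- quantile(positions, c(.25, .5, .75), type = 7)
  expect_equal(bowley_skewness(positions),
               unname((q[3] + q[1] - 2 * q[2]) / (q[3] - q[1])))
  set.seed(13)
  for (i in 1:50) {
    x <- rexp(sample(4:50, 1)) * 100
    s <- bowley_skewness(x)
    if (!is.na(s)) {
      expect_gte(s, -1); expect_lte(s, 1)
      expect_equal(bowley_skewness(2 * x + 17), s)     # affine invariance
      expect_equal(bowley_skewness(-x), -s)            # reflection flips sign
    }
  }
  expect_identical(bowley_skewness(c(1, 2, 3)), NA_real_)
  expect_identical(bowley_skewness(rep(4, 10)), NA_real_)
})

test_that("pair statistics reproduce the planted positional structure", {
  fx <- get_fixtures()$pair_order
  set.seed(14)
  st <- pair_positional_stats(fx$meta$query, fx$promoters,
                              index = get_index("pair_order"))
  expect_gte(st$n_promoters, fx$meta$n_planted)
  expect_lt(st$order_p, 0.01)       # strong planted order bias
  expect_lt(st$bowley, 0)           # TSS-proximal module positions
  expect_gt(st$distance_p, 0.05)    # spacing drawn from the null itself

  fx2 <- get_fixtures()$pair_spacing
  set.seed(15)
  st2 <- pair_positional_stats(fx2$meta$query, fx2$promoters,
                               index = get_index("pair_spacing"))
  expect_lt(st2$distance_p, 1e-6)   # fixed 50 bp spacing
  expect_gt(st2$order_p, 0.05)      # unbiased order

  # a single co-occurring promoter yields no statistics
  p1 <- promoter_set(c("g1", "g2"),
                     c(paste0(strrep("C", 980), "AAAAATTTTTGGGGGCCCCC"),
                       strrep("C", 1000)))
  st3 <- pair_positional_stats("AAAAA,GGGGG", p1)
  expect_identical(st3$n_promoters, 1L)
  expect_true(all(is.na(c(st3$order_p, st3$distance_p, st3$bowley))))
})

test_that("order and distance tests hold their nominal size under the null", {
  set.seed(16)
  n_fix <- 300
  rej_order <- 0; rej_dist <- 0
  nd <- null_distance_distribution(1, 1, iters = 5000)
  for (i in seq_len(n_fix)) {
    ords <- sample(c("a", "b"), 40, replace = TRUE)
    x <- max(sum(ords == "a"), sum(ords == "b"))
    if (order_test(40, x) < 0.05) rej_order <- rej_order + 1
    obs <- null_distance_distribution(1, 1, iters = 30)
    if (distance_test(obs, nd) < 0.05) rej_dist <- rej_dist + 1
  }
  expect_lt(rej_order / n_fix, 0.07)   # exact test is conservative at n = 40
  expect_gt(rej_dist / n_fix, 0.02)
  expect_lt(rej_dist / n_fix, 0.08)
})
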