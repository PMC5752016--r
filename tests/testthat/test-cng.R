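test_that("forward pass matches direct arithmetic, including conventions", {
  # all weights and biases zero: hidden all s(0) = 0.5, output h(0) = 1
  zero <- structure(list(w = matrix(0, 3, 3), b_h = rep(0, 3),
                         v = rep(0, 3), b_o = 0), class = "cng_network")
  expect_identical(cng_forward(zero, c(0.3, 0.5, 0.9)), 1L)
  # 1 hidden neuron, w = (1,0,0), bias 0, v = 1, b = -0.9, input (10, ., .)
  one <- structure(list(w = matrix(c(1, 0, 0), 1, 3), b_h = 0, v = 1,
                        b_o = -0.9), class = "cng_network")
  expect_identical(cng_forward(one, c(10, 0, 0)), 1L)
  expect_identical(cng_forward(one, c(-10, 0, 0)), 0L)

  set.seed(17)
  for (i in 1:100) {
    net <- cng_network(n_hidden = sample(1:5, 1), init_range = 5)
    x <- matrix(runif(300, -1, 1), 100, 3)
    expect_identical(cng_forward(net, x), forward_oracle(net, x))
  }
})

test_that("scoring vetoes negatives and orders by ratio then size", {
  tc <- get_fixtures()$two_cluster
  ts <- cng_training_set(tc$positives, tc$randoms)
  # a network that includes everything necessarily includes the negatives
  everything <- structure(list(w = matrix(0, 3, 3), b_h = rep(0, 3),
                               v = rep(0, 3), b_o = 1), class = "cng_network")
  s <- crmscan:::cng_score(everything, ts)
  expect_true(s$veto)
  expect_identical(s$ratio, -Inf)

  # a band on Bowley skewness around cluster A: in (-0.97, -0.45) roughly
  band <- structure(list(
    w = matrix(c(200, 0, 0, -200, 0, 0), 2, 3, byrow = TRUE),
    b_h = c(190, -90), v = c(5, 5), b_o = -9), class = "cng_network")
  sb <- crmscan:::cng_score(band, ts)
  expect_false(sb$veto)
  expect_identical(sum(sb$pos_in), 16L)   # all of cluster A
  expect_equal(sb$ratio, 16 / max(sb$n_rand, 1))

  # lexicographic order on synthetic score records
  sc <- function(ratio, size) list(ratio = ratio, size = size)
  expect_true(crmscan:::score_better(sc(5, 3), sc(4.9, 100)))
  expect_true(crmscan:::score_better(sc(5, 12), sc(5, 6)))
  expect_false(crmscan:::score_better(sc(-Inf, 50), sc(0.1, 1)))
  # 10 positives over 2 randoms scores 5
  expect_equal(10 / max(2, 1), 5)
})

test_that("later cycles score by uncovered positives and veto stale networks", {
  tc <- get_fixtures()$two_cluster
  ts <- cng_training_set(tc$positives, tc$randoms)
  band <- structure(list(
    w = matrix(c(200, 0, 0, -200, 0, 0), 2, 3, byrow = TRUE),
    b_h = c(190, -90), v = c(5, 5), b_o = -9), class = "cng_network")
  covered_a <- crmscan:::cng_score(band, ts)$pos_in
  s2 <- crmscan:::cng_score(band, ts, uncovered = !covered_a)
  expect_true(s2$veto)   # nothing new
  s3 <- crmscan:::cng_score(band, ts, uncovered = rep(TRUE, nrow(ts$pos)))
  expect_false(s3$veto)
})

test_that("mutation operators change exactly what they claim", {
  set.seed(18)
  net <- cng_network()
  expect_equal(crmscan:::net_to_vec(cng_mutate(net, "incremental", step = 0)),
               crmscan:::net_to_vec(net))
  for (i in 1:20) {
    child <- cng_mutate(net, sample(c("incremental", "disruptive"), 1))
    diff <- crmscan:::net_to_vec(child) != crmscan:::net_to_vec(net)
    expect_lte(sum(diff), 1L)
  }
  cross <- cng_mutate(net, "crossover", other = net)
  expect_equal(crmscan:::net_to_vec(cross), crmscan:::net_to_vec(net))
  other <- cng_network()
  child <- cng_mutate(net, "crossover", other = other)
  vecs <- rbind(crmscan:::net_to_vec(net), crmscan:::net_to_vec(other))
  cv <- crmscan:::net_to_vec(child)
  expect_true(all(vapply(seq_along(cv), function(i) cv[i] %in% vecs[, i], logical(1))))
})

test_that("a separable cluster is learned within one cycle", {
  tc <- get_fixtures()$two_cluster
  pos_a <- tc$positives[tc$positives$cluster == "cluster_a", ]
  ts <- cng_training_set(pos_a, tc$randoms)
  set.seed(19)
  res <- cng_train_cycle(ts, params = cng_params())
  expect_false(res$score$veto)
  expect_gte(sum(res$score$pos_in), 0.9 * nrow(pos_a))
  expect_identical(cng_forward(res$net, ts$neg), rep(0L, 3))
})

test_that("training covers a single tight cluster with one network", {
  tc <- get_fixtures()$two_cluster
  pos_a <- tc$positives[tc$positives$cluster == "cluster_a", ]
  ts <- cng_training_set(pos_a, tc$randoms)
  set.seed(20)
  ens <- cng_train(ts)
  expect_true(all(ens$covered))
  expect_identical(length(ens$networks), 1L)
  g <- glance(ens)
  expect_true(g$coverage_complete)
})

test_that("training is reproducible under a fixed seed", {
  tc <- get_fixtures()$two_cluster
  ts <- cng_training_set(tc$positives, tc$randoms)
  set.seed(21); e1 <- cng_train(ts)
  set.seed(21); e2 <- cng_train(ts)
  expect_identical(e1$members, e2$members)
  expect_equal(e1$networks, e2$networks)
})

test_that("positives coinciding with negative controls are rejected up-front", {
  bad <- tibble::tibble(bowley = c(-0.5, 0), distance_p = c(0.2, 1),
                        order_p = c(0.01, 1))
  expect_error(cng_training_set(bad, bad[0, ]), "negative-control")
})

test_that("category distance follows the containment convention", {
  expect_equal(category_distance(c("a", "b"), c("c", "d")), 1)
  expect_equal(category_distance(c("a", "b"), c("a", "b", "c")), 0)
  expect_equal(category_distance(c("a", "x"), c("a", "b", "c")), 0.5)
  expect_identical(category_distance(character(0), "a"), NA_real_)
})

test_that("ensemble report: symmetric distances, per-network Spearman correlations", {
  # hand-built ensemble over a crafted training set
  pos <- tibble::tibble(id = paste0("p", 1:5),
                        bowley = c(-0.9, -0.7, -0.5, -0.3, -0.1),
                        distance_p = c(0.9, 0.7, 0.5, 0.3, 0.1),
                        order_p = c(0.01, 0.02, 0.03, 0.04, 0.05))
  ts <- cng_training_set(pos, pos[0, ])
  fake <- structure(list(
    networks = list(cng_network(), cng_network()),
    members = list(1:4, 5L),
    scores = list(list(ratio = 4, size = 4, veto = FALSE,
                       pos_in = c(rep(TRUE, 4), FALSE), n_rand = 0L),
                  list(ratio = 1, size = 1, veto = FALSE,
                       pos_in = c(rep(FALSE, 4), TRUE), n_rand = 0L)),
    cycle_rounds = c(3L, 2L), covered = rep(TRUE, 5), ts = ts,
    params = cng_params()), class = "cng_ensemble")
  rep <- ensemble_report(fake)
  expect_equal(rep$distance_matrix, t(rep$distance_matrix))
  expect_equal(diag(rep$distance_matrix), c(0, 0))
  expect_equal(rep$distance_matrix[1, 2], 1)
  # bowley = -distance_p exactly over network 1's members
  expect_equal(rep$correlations$rho_bowley_distance[1], -1)
  expect_equal(rep$correlations$rho_bowley_order[1], 1)
  # single-member network: not computed
  expect_true(is.na(rep$correlations$rho_bowley_distance[2]))
})

test_that("random-pair positional arm substitutes neutral values when undefined", {
  set.seed(22)
  proms <- generate_promoters(12, region_length = 300)
  rp <- random_positional_stats(proms, n_pairs = 6, iters = 200)
  expect_identical(nrow(rp), 6L)
  expect_true(all(rp$order_p > 0 & rp$order_p <= 1))
  expect_true(all(rp$distance_p > 0 & rp$distance_p <= 1))
  expect_true(all(rp$bowley >= -1 & rp$bowley <= 1))
})
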