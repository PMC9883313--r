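# CV permutation tests, Mantel test, modularity clustering and social
# differentiation.

test_that("association CV matches hand computations", {
  m <- matrix(0.3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  expect_equal(association_cv(m), 0)
  m2 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m2[1, 2] <- m2[2, 1] <- 0.2
  m2[1, 3] <- m2[3, 1] <- 0.6
  m2[2, 3] <- m2[3, 2] <- 0  # a zero dyad inflates the all-dyad CV
  # nonzero dyads {0.2, 0.6}: mean 0.4, population sd 0.2 -> CV 0.5
  expect_equal(association_cv(m2, nonzero_only = TRUE), 0.5)
  expect_gt(association_cv(m2), association_cv(m2, nonzero_only = TRUE))
  expect_error(association_cv(matrix(0, 3, 3)), "zero")
})

test_that("checkerboard flips preserve per-day degrees and identification sets", {
  rec <- simulate_identifications(
    simulation_config(n_individuals = 16, n_units = 4, n_days = 10),
    seed = 6)
  assoc <- daily_associations(rec, "probabilistic", threshold = 10)
  before_deg <- lapply(seq_along(assoc$days), function(k) {
    e <- assoc$edges[[k]]
    sort(table(c(e[, 1], e[, 2])))
  })
  pt <- permute_within_days(assoc, n_permutations = 20, n_trials = 200,
                            seed = 5, check_degrees = TRUE)
  expect_gt(pt$n_flips, 0)
  ids <- pt$ids
  for (k in seq_along(assoc$days)) {
    e <- pt$final_edges[[k]]
    if (nrow(e) == 0) next
    after <- sort(table(c(ids[e[, 1]], ids[e[, 2]])))
    expect_equal(after, before_deg[[k]])
  }
})

test_that("permutation P values follow the add-one convention and seed reproducibly", {
  cfg <- strong_signal_config()
  rec <- simulate_identifications(cfg, seed = 4)
  assoc <- daily_associations(rec, "probabilistic", threshold = 8)
  pt1 <- permute_within_days(assoc, n_permutations = 100, n_trials = 300,
                             seed = 11)
  pt2 <- permute_within_days(assoc, n_permutations = 100, n_trials = 300,
                             seed = 11)
  expect_identical(pt1$null, pt2$null)
  expect_identical(pt1$p_value, pt2$p_value)
  # planted preferences: the observed CV should beat essentially the whole
  # null distribution, giving the minimal attainable P of 1/(n+1)
  expect_equal(pt1$p_value, 1 / 101, tolerance = 0.05)

  # a statistic that flips cannot change: only one dyad ever associated
  rec1 <- data.frame(
    individual = rep(c("A", "B", "C"), 4),
    event = rep(sprintf("e%d", 1:4), each = 3),
    ordinal = rep(c(1, 1, 50), 4),
    date = rep(as.Date("2001-06-01") + 0:3, each = 3))
  a1 <- daily_associations(rec1, "same_frame")
  p1 <- permute_within_days(a1, n_permutations = 50, n_trials = 50, seed = 1)
  expect_equal(p1$p_value, 1, tolerance = 1e-12)
  expect_equal(p1$n_flips, 0)
})

test_that("Mantel test agrees with hand Pearson and an independent package", {
  skip_if_not_installed("vegan")
  # 6-individual block structure
  ids <- letters[1:6]
  m <- matrix(0.05, 6, 6, dimnames = list(ids, ids))
  m[1:3, 1:3] <- 0.8
  m[4:6, 4:6] <- 0.7
  m[2, 3] <- m[3, 2] <- 0.4
  diag(m) <- 0
  memb <- setNames(rep(c("g1", "g2"), each = 3), ids)
  same <- outer(memb, memb, "==") * 1
  ut <- upper.tri(m)
  r_hand <- cor(m[ut], same[ut])
  res <- mantel_association_test(m, memb, n_permutations = 200, seed = 2)
  expect_equal(res$matrix_correlation, r_hand, tolerance = 1e-12)
  veg <- vegan::mantel(as.dist(m), as.dist(same), permutations = 200)
  expect_equal(res$matrix_correlation, unname(veg$statistic),
               tolerance = 1e-10)
  # with 6 individuals only choose(6,3)/2 = 10 distinct 3+3 splits exist,
  # so the attainable P is floored near 0.1
  expect_lt(res$p_value, 0.15)

  # perfect block structure: correlation 1
  m2 <- matrix(0, 6, 6, dimnames = list(ids, ids))
  m2[1:3, 1:3] <- 1; m2[4:6, 4:6] <- 1; diag(m2) <- 0
  expect_equal(mantel_association_test(
    m2, memb, n_permutations = 50, seed = 1)$matrix_correlation, 1)
})

test_that("Mantel correlation is invariant to relabeling and joint permutation", {
  set.seed(31)
  ids <- sprintf("i%02d", 1:12)
  m <- matrix(runif(144), 12, 12, dimnames = list(ids, ids))
  m <- (m + t(m)) / 2; diag(m) <- 0
  memb <- setNames(rep(c("x", "y", "z"), each = 4), ids)
  r0 <- mantel_association_test(m, memb, n_permutations = 10,
                                seed = 1)$matrix_correlation
  relab <- setNames(c(x = "unitA", y = "unitB", z = "unitC")[memb], ids)
  expect_equal(mantel_association_test(
    m, relab, n_permutations = 10, seed = 1)$matrix_correlation, r0)
  perm <- sample(12)
  mp <- m[perm, perm]
  expect_equal(mantel_association_test(
    mp, memb, n_permutations = 10, seed = 1)$matrix_correlation, r0,
    tolerance = 1e-12)

  expect_error(mantel_association_test(
    m, setNames(rep("one", 12), ids), 10), "single group")
  expect_error(mantel_association_test(
    m, setNames(as.character(1:12), ids), 10), "own group")
})

test_that("null membership labels on a structureless matrix are not significant", {
  set.seed(55)
  ids <- sprintf("i%02d", 1:20)
  m <- matrix(runif(400, 0, 0.3), 20, 20, dimnames = list(ids, ids))
  m <- (m + t(m)) / 2; diag(m) <- 0
  ps <- sapply(1:20, function(k) {
    memb <- setNames(sample(rep(c("a", "b"), 10)), ids)
    mantel_association_test(m, memb, n_permutations = 100)$p_value
  })
  expect_gt(mean(ps), 0.2)  # roughly uniform P under the null
})

test_that("two disconnected triangles split into two clusters with Q = 1/2", {
  part <- newman_communities(make_fixture("two-triangles"))
  expect_identical(part$n_clusters, 2L)
  expect_identical(sort(part$cluster_sizes), c(3L, 3L))
  expect_equal(part$q, 0.5, tolerance = 1e-12)
  w <- make_fixture("two-triangles")
  expect_equal(part$q, direct_q(w, part$assignment), tolerance = 1e-10)
})

test_that("modularity recomputation and igraph agree on random and simulated graphs", {
  set.seed(77)
  for (rep in 1:8) {
    n <- sample(6:25, 1)
    m <- matrix(runif(n * n) * rbinom(n * n, 1, 0.3), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(sprintf("v%d", 1:n), sprintf("v%d", 1:n))
    part <- newman_communities(m)
    expect_equal(part$q, direct_q(m, part$assignment), tolerance = 1e-10)
    if (sum(m) > 0) {
      g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                               weighted = TRUE)
      expect_equal(part$q,
                   igraph::modularity(g, part$assignment,
                                      weights = igraph::E(g)$weight),
                   tolerance = 1e-10)
    }
  }
  # complete graph with equal weights: no beneficial split
  cm <- matrix(1, 8, 8); diag(cm) <- 0
  dimnames(cm) <- list(letters[1:8], letters[1:8])
  expect_identical(newman_communities(cm)$n_clusters, 1L)
  # all-zero weights: single cluster, Q = 0
  zm <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  pz <- newman_communities(zm)
  expect_identical(pz$n_clusters, 1L)
  expect_equal(pz$q, 0)
  expect_error(newman_communities(matrix(numeric(0), 0, 0)), "empty")
})

test_that("a planted four-unit society is recovered exactly at high signal", {
  rec <- simulate_identifications(strong_signal_config(), seed = 1)
  assoc <- daily_associations(rec, "probabilistic", threshold = 8)
  hw <- hwi_matrix(assoc)
  part <- newman_communities(hw)
  unit <- unit_membership(rec)
  expect_identical(part$n_clusters, 4L)
  expect_equal(adjusted_rand(part$assignment, unit[names(part$assignment)]),
               1)
  mt <- mantel_association_test(hw, unit, n_permutations = 100, seed = 9)
  expect_gt(mt$matrix_correlation, 0.9)
  expect_equal(mt$p_value, 1 / 101)
})

test_that("social differentiation separates homogeneous from bimodal societies", {
  # homogeneous: every dyad at the same moderate rate with ample sampling
  hom <- social_differentiation(x = rep(10L, 300), d = rep(20L, 300))
  expect_true(hom$boundary)
  expect_equal(hom$s, 0)

  # bimodal: a fifth of dyads always associated, the rest never -> the
  # latent distribution has mean 0.2 and sd 0.4, CV 2
  bim <- social_differentiation(x = rep(c(20L, 0L), times = c(100, 400)),
                                d = rep(20L, 500))
  expect_gt(bim$s, 1)

  # maximized likelihood dominates the 16-point start grid
  set.seed(12)
  p <- rbeta(200, 1.2, 3)
  x <- rbinom(200, 15, p)
  fit <- fit_beta_binomial(x, rep(15L, 200))
  expect_true(all(fit$loglik >= fit$start_logliks - 1e-6))
  expect_error(fit_beta_binomial(integer(0), integer(0)), "no dyads")
  expect_error(fit_beta_binomial(5, 3), "0 <= x <= d")
})
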