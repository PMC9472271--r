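test_that("tanimoto similarity follows the set algebra", {
  v <- function(bits, n = 8) { x <- integer(n); x[bits] <- 1L; x }
  expect_equal(tanimoto(v(c(1, 2, 3)), v(c(1, 2, 3))), 1.0)
  expect_equal(tanimoto(v(c(1, 2)), v(c(5, 6))), 0.0)
  expect_equal(tanimoto(v(c(1, 2, 3)), v(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(integer(8), integer(8)), 1.0)   # all-zero convention
  expect_error(tanimoto(v(1, 8), v(1, 16)), class = "toxhybrid_dimension_error")
  set.seed(11)
  for (i in 1:20) {
    a <- rbinom(32, 1, 0.3); b <- rbinom(32, 1, 0.3)
    expect_equal(tanimoto(a, b), oracle_tanimoto(a, b))
  }
})

test_that("manhattan distance is the elementwise absolute sum", {
  expect_equal(manhattan(c(1, 2), c(1, 2)), 0)
  expect_equal(manhattan(c(0, 0), c(1, 2)), 3)
  expect_error(manhattan(1:3, 1:4), class = "toxhybrid_dimension_error")
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(manhattan(x, y), oracle_manhattan(x, y))
    expect_equal(manhattan(x, y), manhattan(y, x))            # symmetry
    z <- rnorm(5)                                             # triangle
    expect_lte(manhattan(x, z), manhattan(x, y) + manhattan(y, z))
  }
})

test_that("neighbour search returns the exact training point and breaks ties by index", {
  x <- matrix(c(0, 0, 1, 1, 2, 2), ncol = 2, byrow = TRUE)
  m <- tox_knn(x, c(10, 20, 30), "descriptor", k = 1)
  expect_equal(predict(m, x[2, , drop = FALSE]), 20)
  # five equidistant points: lowest two indices win
  xe <- matrix(rep(c(1, 0), 5), ncol = 2, byrow = TRUE)
  me <- tox_knn(rbind(xe, c(-1, 0)), c(1:5, 9), "descriptor", k = 2)
  nb <- find_neighbors(me, matrix(c(1, 0), 1), k = 2)
  expect_equal(as.integer(nb[1, ]), c(1L, 2L))
  expect_error(find_neighbors(me, matrix(c(1, 0), 1), k = 10),
               class = "toxhybrid_parameter_error")
})

test_that("descriptor-mode kNN agrees exactly with the exhaustive oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 50
    x <- matrix(rnorm(n * 4), n)
    y <- rnorm(n)
    q <- matrix(rnorm(3 * 4), 3)
    k <- sample(1:7, 1)
    m <- tox_knn(x, y, "descriptor", k = k)
    sc <- oracle_scale(x, q)
    for (j in 1:3) {
      expect_equal(as.integer(find_neighbors(m, q[j, , drop = FALSE])),
                   oracle_neighbors(sc$train, sc$query[j, ], k, "descriptor"))
      expect_equal(predict(m, q[j, , drop = FALSE]),
                   oracle_knn_predict(sc$train, y, sc$query[j, ], k, "descriptor"))
    }
  }
})

test_that("fingerprint-mode kNN agrees exactly with the exhaustive oracle", {
  set.seed(22)
  for (rep in 1:5) {
    n <- 40
    x <- matrix(rbinom(n * 64, 1, 0.2), n)
    y <- rnorm(n)
    q <- matrix(rbinom(2 * 64, 1, 0.2), 2)
    k <- sample(1:5, 1)
    m <- tox_knn(x, y, "fingerprint", k = k)
    for (j in 1:2) {
      expect_equal(as.integer(find_neighbors(m, q[j, , drop = FALSE])),
                   oracle_neighbors(x, q[j, ], k, "fingerprint"))
      expect_equal(predict(m, q[j, , drop = FALSE]),
                   oracle_knn_predict(x, y, q[j, ], k, "fingerprint"))
    }
  }
})

test_that("unweighted predictions interpolate the training targets", {
  set.seed(23)
  x <- matrix(rnorm(200), 50)
  y <- runif(50, -3, 7)
  m <- tox_knn(x, y, "descriptor", k = 4)
  p <- predict(m, matrix(rnorm(40), 10))
  expect_true(all(p >= min(y) & p <= max(y)))
  expect_equal(predict(m, x[5, , drop = FALSE], k = 50), mean(y))
  # k = 3 mean of neighbour targets {1,2,3}
  xm <- matrix(c(0, 1, 2, 100), ncol = 1)
  mm <- tox_knn(xm, c(1, 2, 3, 50), "descriptor", k = 3)
  expect_equal(predict(mm, matrix(1, 1, 1)), 2.0)
})

test_that("column rescaling does not change neighbour sets (z-scaling absorbs it)", {
  set.seed(24)
  x <- matrix(rnorm(120), 30)
  y <- rnorm(30)
  q <- matrix(rnorm(8), 2)
  m1 <- tox_knn(x, y, "descriptor", k = 3)
  x2 <- x; x2[, 2] <- x2[, 2] * 1000
  q2 <- q; q2[, 2] <- q2[, 2] * 1000
  m2 <- tox_knn(x2, y, "descriptor", k = 3)
  expect_equal(find_neighbors(m1, q), find_neighbors(m2, q2), ignore_attr = TRUE)
})

test_that("a duplicated query with known target dominates at k = 1", {
  set.seed(25)
  x <- matrix(rnorm(80), 20)
  q <- matrix(rnorm(4), 1)
  m <- tox_knn(rbind(x, q), c(rnorm(20), 7.25), "descriptor", k = 1)
  expect_equal(predict(m, q), 7.25)
})

test_that("leave-one-out exclusion removes the self-match", {
  x <- matrix(c(0, 0.1, 5, 5.1), ncol = 1)
  y <- c(1, 2, 3, 4)
  m <- tox_knn(x, y, "descriptor", k = 1)
  expect_equal(predict(m, x, k = 1, exclude_self = 1:4), c(2, 1, 4, 3))
})

test_that("cross-validated k selection recovers exact-duplicate structure", {
  # every point duplicated with identical target: k=1 reconstructs exactly,
  # k=5 mixes distinct targets
  set.seed(26)
  base <- matrix(runif(40 * 2, 0, 10), 40)
  x <- rbind(base, base + 1e-9)
  y <- rep(seq_len(40), 2)
  plan <- cv_plan(validation_ratios = c(0.1, 0.2), candidate_ks = c(1, 5),
                  repeats = 3, seed = 9)
  res <- select_k(x, y, "descriptor", plan)
  expect_equal(res$best_k, 1L)
  res2 <- select_k(x, y, "descriptor", plan)
  expect_identical(res$score_table, res2$score_table)   # seeded determinism
  one <- select_k(x, y, "descriptor",
                  cv_plan(validation_ratios = 0.2, candidate_ks = 3,
                          repeats = 2, seed = 1))
  expect_equal(one$best_k, 3L)
  expect_error(
    select_k(x, y, "descriptor",
             cv_plan(validation_ratios = 0.3, candidate_ks = c(1, 79),
                     repeats = 1, seed = 1)),
    class = "toxhybrid_parameter_error")
})

test_that("published neighbour-count presets are exposed", {
  expect_equal(preset_k("desc"), c(2L, 4L, 5L, 6L, 8L))
  expect_equal(preset_k("fpn"), c(2L, 5L, 7L, 12L, 14L))
})
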