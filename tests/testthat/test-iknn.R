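test_that("kernel similarity matches its closed form", {
  expect_equal(kernel_distance(c(1, 2), c(1, 2)), 1)
  v <- c(0.3, -0.4)                       # ||v||^2 = 0.25
  expect_equal(kernel_distance(c(0, 0), v, bandwidth = 0.25), exp(-1))
  expect_equal(kernel_distance(c(0, 0), c(sqrt(0.5), 0), bandwidth = 1),
               exp(-0.5))
  expect_error(kernel_distance(1:2, 1:3), class = "shape_error")
  expect_error(kernel_distance(1:2, 2:3, bandwidth = 0),
               class = "invalid_parameter")
})

test_that("isolation weight handles same-label, coincident and toy cases", {
  nb <- rbind(c(0, 0), c(1, 0), c(0, 1))
  # all neighbours share the candidate's label -> every factor is 1
  expect_equal(lambda_weight(c(0.5, 0.5), "A", nb, c("A", "A", "A")), 1)
  # an opposite-class neighbour coincident with the candidate -> zero factor
  expect_equal(lambda_weight(c(0, 0), "A", nb, c("B", "A", "A")), 0)
  # single opposite-class neighbour at squared distance 1 (d = e^-1)
  xj <- c(0, 0)
  nb3 <- rbind(c(1, 0), c(0.1, 0), c(0, 0.2))
  expect_equal(lambda_weight(xj, "A", nb3, c("B", "A", "A")), 1 - exp(-1))
})

test_that("neighbour informativeness is a probability distribution", {
  set.seed(5)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c("CG", "EG"), 10)
  for (cfg in list(iknn_config(), iknn_config(bandwidth_rule = "literal"))) {
    for (i in c(1, 7, 20)) {
      for (k in c(3, 5, 10)) {
        p <- informativeness(i, k, x, y, cfg)
        expect_length(p, k)
        expect_true(all(p >= 0))
        expect_lt(abs(sum(p) - 1), 1e-9)
      }
    }
  }
})

test_that("when all neighbours share one label, informativeness is proportional to the kernel", {
  # 6 tight class-A points around one query, class-B points far away so they
  # never enter the neighbourhood; eta = 1 for every neighbour.
  set.seed(6)
  xa <- matrix(rnorm(14, sd = 0.3), 7, 2)
  xb <- matrix(rnorm(10, mean = 50, sd = 0.3), 5, 2)
  x <- rbind(xa, xb)
  y <- rep(c("A", "B"), c(7, 5))
  cfg <- iknn_config(bandwidth_rule = "literal", standardize = FALSE)
  p <- informativeness(1, 5, x, y, cfg)
  nb <- as.integer(names(p))
  d <- vapply(nb, function(j) exp(-sum((x[1, ] - x[j, ])^2)), numeric(1))
  expect_equal(unname(p), d / sum(d), tolerance = 1e-12)
})

test_that("mean scores hit the extremes for isolated and embedded points", {
  set.seed(7)
  # point 1: class A at the centre of a tight class-B cluster; remaining
  # class-A points far away -> its 10 nearest neighbours are all B.
  xb <- matrix(rnorm(30, sd = 0.5), 15, 2)
  xa_far <- matrix(rnorm(20, mean = 30, sd = 0.5), 10, 2)
  x <- rbind(c(0, 0), xb, xa_far)
  y <- c("A", rep("B", 15), rep("A", 10))
  sc <- mean_informativeness_score(x, y, iknn_config(standardize = FALSE))
  expect_equal(nrow(sc$pairs), 25)
  expect_equal(sc$s_bar[[1]], 1)          # every vote disagrees
  expect_equal(sc$s_bar[[17]], 0)         # deep inside its own class
  expect_true(all(sc$s_bar >= 0 & sc$s_bar <= 1))
  expect_equal(rowMeans(sc$scores), sc$s_bar)
})

test_that("mean scores equal the brute-force oracle to 1e-12", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 30
    d <- sample(2:5, 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- sample(c("CG", "EG"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    for (cfg in list(iknn_config(),
                     iknn_config(bandwidth_rule = "literal"))) {
      got <- mean_informativeness_score(x, y, cfg)$s_bar
      want <- oracle_sbar(x, y,
                          bandwidth = if (cfg$bandwidth_rule == "literal") 1 else NULL)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("flipping a point's own label complements its mean score exactly", {
  set.seed(8)
  x <- matrix(rnorm(60), 30, 2)
  y <- rep(c("CG", "EG"), 15)
  base <- mean_informativeness_score(x, y)$s_bar
  for (i in c(1, 12, 30)) {
    y2 <- y
    y2[i] <- ifelse(y[i] == "CG", "EG", "CG")
    flipped <- mean_informativeness_score(x, y2)$s_bar
    expect_identical(flipped[[i]], 1 - base[[i]])
  }
})

test_that("score values are invariant under rigid transforms of the feature matrix", {
  set.seed(9)
  x <- matrix(rnorm(80), 20, 4)
  y <- rep(c("CG", "EG"), 10)
  cfg <- iknn_config(standardize = FALSE)
  ref <- mean_informativeness_score(x, y, cfg)$s_bar
  theta <- 0.7
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- x %*% rot + matrix(c(5, -2, 0.5, 3), 20, 4, byrow = TRUE)
  expect_equal(mean_informativeness_score(moved, y, cfg)$s_bar, ref,
               tolerance = 1e-9)
})

test_that("filtering discards the round-half-up count in ranked order", {
  set.seed(10)
  x <- rbind(matrix(rnorm(152), 76, 2), matrix(rnorm(152, 3), 76, 2))
  y <- rep(c("CG", "EG"), each = 76)          # n = 152
  idx <- sample(152)
  x <- x[idx, ]; y <- y[idx]
  res <- filter_points(x, y, iknn_config(discard_fraction = 0.05))
  expect_equal(res$n_discard, 8)              # round(0.05 * 152)
  expect_equal(length(res$discarded), 8)
  expect_equal(sort(c(res$retained, res$discarded)), 1:152)
  # discarded points carry the highest mean scores
  expect_gte(min(res$s_bar[res$discarded]), max(res$s_bar[res$retained]) - 1e-12)

  res0 <- filter_points(x, y, iknn_config(discard_fraction = 0))
  expect_equal(length(res0$discarded), 0)
  expect_equal(res0$retained, 1:152)
})

test_that("cg-only scope discards only control points, counted against controls", {
  set.seed(11)
  x <- rbind(matrix(rnorm(120), 60, 2), matrix(rnorm(80, 3), 40, 2))
  y <- rep(c("CG", "EG"), c(60, 40))
  res <- filter_points(x, y, iknn_config(discard_fraction = 0.05,
                                         scope = "cg-only"))
  expect_equal(res$n_discard, 3)              # round(0.05 * 60)
  expect_true(all(y[res$discarded] == "CG"))
})

test_that("filtering refuses to empty a class", {
  set.seed(12)
  xb <- matrix(rnorm(38, sd = 0.4), 19, 2)
  x <- rbind(c(0, 0), xb)
  y <- c("A", rep("B", 19))                   # lone A point scores worst
  expect_error(filter_points(x, y, iknn_config(discard_fraction = 0.05)),
               class = "class_depletion")
})

test_that("planted label flips receive higher mean scores than clean points", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    bench <- make_flip_benchmark()
    s <- mean_informativeness_score(bench$x, bench$y)$s_bar
    clean <- setdiff(seq_along(s), bench$flipped)
    hits <- hits + (mean(s[bench$flipped]) > mean(s[clean]))
  }
  expect_gte(hits, 19)
})
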