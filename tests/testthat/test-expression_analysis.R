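test_that("average_replicates takes per-condition means", {
  sim <- simulate_expression(3, n_patterns = 2, seed = 3)
  avg <- average_replicates(sim$table)
  expect_equal(dim(avg), c(6, 7))
  g <- rownames(avg)[1]
  cond <- unique(sim$table$conditions)[1]
  expect_equal(avg[g, cond],
               mean(sim$table$data[g, sim$table$conditions == cond]))
})

test_that("zscore_rows yields mean 0, sample variance 1 (property)", {
  set.seed(12)
  for (trial in 1:20) {
    m <- matrix(rnorm(7 * 15, sd = runif(1, 0.5, 20),
                      mean = runif(1, -5, 5)), nrow = 15)
    z <- zscore_rows(m)
    expect_lt(max(abs(rowMeans(z))), 1e-9)
    expect_lt(max(abs(apply(z, 1, var) - 1)), 1e-9)
  }
  expect_equal(zscore_rows(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  z1 <- matrix(c(-1, 0, 1), 1)
  expect_equal(zscore_rows(z1), z1, tolerance = 1e-12)  # idempotence
  expect_error(zscore_rows(matrix(5, 1, 7, dimnames = list("g1", NULL))), "g1")
})

test_that("cosine_similarity: values, symmetry, scale invariance", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  set.seed(8)
  for (trial in 1:20) {
    u <- rnorm(7); v <- rnorm(7); s <- runif(1, 0.1, 50)
    expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
    expect_equal(cosine_similarity(s * u, v), cosine_similarity(u, v),
                 tolerance = 1e-12)
    expect_lte(abs(cosine_similarity(u, v)), 1)
  }
})

test_that("pearson_and_transform applies the log-ratio transform", {
  u <- c(1, 2, 3, 4, 5)
  self <- pearson_and_transform(u, u)
  expect_true(self$infinite)
  expect_equal(self$r, 1)
  # construct R = 0.5 via known bivariate values
  v <- c(2, 1, 4, 3, 5)
  pr <- pearson_and_transform(u, v)
  expect_equal(pr$transformed_r, log((1 + pr$r) / (1 - pr$r)),
               tolerance = 1e-12)
  orth <- pearson_and_transform(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(orth$r, 0)
  expect_equal(orth$transformed_r, 0)
  expect_error(pearson_and_transform(u, rep(2, 5)), "constant")
})

test_that("classify_quadrant is an exhaustive, disjoint partition", {
  expect_identical(as.character(classify_quadrant(0.9805, 13)), "A")
  expect_identical(as.character(classify_quadrant(0.40, 29)), "C")
  expect_identical(as.character(classify_quadrant(0.45, 62)), "D")
  expect_identical(as.character(classify_quadrant(0.8, 70)), "B")
  # boundaries fall on the low side
  expect_identical(as.character(classify_quadrant(0.5, 50)), "C")
  expect_identical(as.character(classify_quadrant(0.5000001, 50)), "A")
  grid <- expand.grid(cos = c(-1, 0, 0.5, 0.50001, 1),
                      div = c(0, 50, 50.0001, 100))
  q <- classify_quadrant(grid$cos, grid$div)
  expect_false(any(is.na(q)))
  expect_error(classify_quadrant(1.2, 10), "\\[-1, 1\\]")
  expect_error(classify_quadrant(0.2, 101), "\\[0, 100\\]")
})

test_that("gene_best_match finds best hits and is asymmetric", {
  sim <- simulate_expression(10, n_patterns = 4, noise_sd = 0, seed = 21)
  z <- zscore_rows(average_replicates(sim$table))
  self <- gene_best_match(z, z)
  expect_true(all(abs(self$best$cosine - 1) < 1e-12))
  expect_equal(self$mean, 1)

  a <- matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE,
              dimnames = list(c("a1", "a2"), NULL))
  b <- matrix(c(1, 0.2, 0, 0.9, 0.1, 0.4, -1, 0.3, 0.2), 3, byrow = TRUE,
              dimnames = list(c("b1", "b2", "b3"), NULL))
  ab <- gene_best_match(a, b)
  ba <- gene_best_match(b, a)
  expect_false(isTRUE(all.equal(ab$mean, ba$mean)))
  s <- matrix(c(1, 1), 1, dimnames = list("s", NULL))
  t <- matrix(c(1, 0), 1, dimnames = list("t", NULL))
  st <- gene_best_match(s, t)
  expect_equal(st$best$cosine, 1 / sqrt(2), tolerance = 1e-12)
  expect_true(is.na(st$sd))
})

test_that("regress_expression_vs_constraint matches OLS closed forms", {
  rec <- data.frame(ka = c(0.1, 0.25, 0.3, 0.42, 0.5),
                    transformed_r = c(2.2, 1.8, 1.5, 1.1, 0.6))
  got <- regress_expression_vs_constraint(rec, "ka", "transformed_r")
  x <- rec$ka; y <- rec$transformed_r
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(got$slope, slope, tolerance = 1e-12)
  expect_equal(got$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_equal(got$r, cor(x, y), tolerance = 1e-12)

  col <- data.frame(ka = 1:4, transformed_r = 3 * (1:4) - 1)
  expect_equal(regress_expression_vs_constraint(col, "ka", "transformed_r")$r, 1)
  # expression_divergence falls back to 1 - cosine
  rec$cosine <- c(0.9, 0.8, 0.85, 0.7, 0.6)
  gd <- regress_expression_vs_constraint(rec, "ka", "expression_divergence")
  expect_equal(gd$r, cor(rec$ka, 1 - rec$cosine), tolerance = 1e-12)
  # infinite transformed R dropped with a warning
  rec2 <- rec
  rec2$transformed_r[1] <- Inf
  expect_warning(regress_expression_vs_constraint(rec2, "ka", "transformed_r"),
                 "dropped")
  expect_error(regress_expression_vs_constraint(
    data.frame(ka = 1:4, transformed_r = rep(1, 4)), "ka", "transformed_r"),
    "zero variance|degenerate")
})

test_that("pair_expression_stats joins pairs and flags absent genes", {
  sim <- simulate_expression(8, n_patterns = 4, within_pair_cosine = 1,
                             noise_sd = 0, seed = 14)
  stats <- pair_expression_stats(sim$table, sim$pairs)
  expect_equal(nrow(stats), 8)
  expect_true(all(abs(stats$cosine - 1) < 1e-9))

  extra <- sim$pairs
  extra[9, c("gene1", "gene2", "class", "replicon1", "replicon2")] <-
    list("ghost1", "ghost2", "in", "CI", "CI")
  expect_warning(st2 <- pair_expression_stats(sim$table, extra), "dropped")
  expect_equal(nrow(st2), 8)
})
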