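test_that("polychoric matrix has unit diagonal, symmetry and independence limit", {
  bank <- generate_bank(3, seed = 1)
  withr::with_seed(2, {
    # items 1-2 share a trait; item 3 driven by an independent trait
    th <- rnorm(5000)
    rm <- simulate_responses(bank[1:2, ], th, seed = 3)
    rm3 <- simulate_responses(bank[3, ], rnorm(5000), seed = 4)
    rm$item03 <- rm3$item03
  })
  r <- polychoric_matrix(rm, bank, "scale")
  expect_equal(diag(r), setNames(rep(1, 3), bank$item_id))
  expect_equal(r, t(r))
  expect_true(all(abs(r) <= 1))
  expect_lt(abs(r["item01", "item03"]), 0.05)
  expect_lt(abs(r["item02", "item03"]), 0.05)
  expect_gt(r["item01", "item02"], 0.3)

  # permutation equivariance
  r2 <- polychoric_matrix(rm, bank[c(3, 1, 2), ], "scale")
  expect_equal(r2[bank$item_id, bank$item_id], r, tolerance = 1e-6)

  const <- rm
  const$item01 <- 1L
  expect_error(polychoric_matrix(const, bank, "scale"), "item01")
})

test_that("polychoric estimate matches a brute-force bivariate-normal grid search", {
  bank <- generate_bank(2, seed = 5)
  rm <- simulate_responses(bank, rnorm(800), seed = 6)
  # dichotomize both items at >= 1 so the oracle is a 2x2 table
  x <- as.integer(rm$item01 >= 1)
  y <- as.integer(rm$item02 >= 1)
  est <- polychoric_corr(x, y)

  # oracle: Riemann-sum bivariate normal rectangle probabilities on a rho grid
  a <- qnorm(1 - mean(x))
  b <- qnorm(1 - mean(y))
  grid_ll <- function(rho) {
    xs <- seq(-6, 6, length.out = 601)
    h <- xs[2] - xs[1]
    dens <- outer(xs, xs, function(u, v) {
      exp(-(u^2 - 2 * rho * u * v + v^2) / (2 * (1 - rho^2))) /
        (2 * pi * sqrt(1 - rho^2))
    }) * h^2
    p11 <- sum(dens[xs >= a, xs >= b])
    p10 <- sum(dens[xs >= a, xs < b])
    p01 <- sum(dens[xs < a, xs >= b])
    p00 <- sum(dens[xs < a, xs < b])
    n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
    n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
    n11 * log(p11) + n10 * log(p10) + n01 * log(p01) + n00 * log(p00)
  }
  rhos <- seq(-0.95, 0.95, by = 0.005)
  oracle <- rhos[which.max(vapply(rhos, grid_ll, numeric(1)))]
  expect_equal(est, oracle, tolerance = 0.015)
})

test_that("one-factor fit is exact on one-factor truth and null on identity", {
  lam <- rep(0.7, 8)
  r <- tcrossprod(lam)
  diag(r) <- 1
  f <- fit_one_factor(r, n = 500)
  expect_lt(max(abs(f$residuals)), 1e-6)
  expect_equal(f$fit$cfi, 1)
  expect_lt(f$fit$srmr, 1e-6)
  expect_equal(unname(abs(f$loadings)), lam, tolerance = 1e-4)

  f0 <- fit_one_factor(diag(6), n = 200)
  expect_lt(max(abs(f0$loadings)), 0.02)
  expect_lt(f0$fit$srmr, 1e-6)

  expect_error(fit_one_factor(r, n = 5), "exceed")
})

test_that("forcing two-factor data into one factor worsens RMSEA and SRMR", {
  lam <- rep(0.7, 8)
  one <- tcrossprod(lam); diag(one) <- 1
  two <- one
  # two blocks of four items loading on separate, weakly related factors
  block <- outer(1:8, 1:8, function(i, j) (i <= 4) == (j <= 4))
  two[!block] <- 0.49 * 0.3
  diag(two) <- 1
  f1 <- fit_one_factor(one, n = 500)
  f2 <- fit_one_factor(two, n = 500)
  expect_gt(f2$fit$srmr, f1$fit$srmr)
  expect_gt(f2$fit$rmsea, f1$fit$rmsea)
})

test_that("local-dependence flagging respects the threshold and sorts descending", {
  res <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(nrow(flag_local_dependence(res)), 0)

  res["a", "b"] <- res["b", "a"] <- 0.25
  res["c", "d"] <- res["d", "c"] <- 0.31
  fl <- flag_local_dependence(res, threshold = 0.2)
  expect_equal(fl$item1, c("c", "a"))
  expect_equal(fl$residual, c(0.31, 0.25))

  res2 <- res
  res2["a", "c"] <- res2["c", "a"] <- 0.01
  fl0 <- flag_local_dependence(res2, threshold = 0)
  expect_equal(nrow(fl0), 3)  # every positive-residual pair
})

test_that("count_item_pairs equals exhaustive pair enumeration", {
  expect_identical(count_item_pairs(c(16, 6, 12, 16)), 321L)
  expect_identical(count_item_pairs(2), 1L)
  expect_identical(count_item_pairs(c(3, 4)), 9L)
  withr::with_seed(11, {
    for (rep in 1:20) {
      sizes <- sample(1:20, sample(1:5, 1), replace = TRUE)
      brute <- sum(vapply(sizes, function(k) {
        if (k < 2) return(0L)
        nrow(t(utils::combn(k, 2)))
      }, integer(1)))
      expect_identical(count_item_pairs(sizes), as.integer(brute))
    }
  })
})

test_that("scalability is 1 on Guttman data, ~0 on independence, and matches brute force", {
  # perfect Guttman: items are step functions of one underlying total
  score <- rep(0:8, each = 5)
  g <- tibble::tibble(person_id = sprintf("g%02d", seq_along(score)))
  b3 <- generate_bank(3, seed = 12)
  g$item01 <- as.integer(pmin(pmax(score - 1, 0), 2))
  g$item02 <- as.integer(pmin(pmax(score - 3, 0), 2))
  g$item03 <- as.integer(pmin(pmax(score - 5, 0), 2))
  sg <- scalability(g, b3, "scale")
  expect_equal(sg$pairwise_h$h, rep(1, 3), tolerance = 1e-12)
  expect_equal(sg$scale_h, 1, tolerance = 1e-12)

  # independent items
  b4 <- generate_bank(4, seed = 13)
  ind <- tibble::tibble(person_id = sprintf("i%04d", 1:5000))
  withr::with_seed(14, {
    for (id in b4$item_id) ind[[id]] <- sample(0:2, 5000, TRUE)
  })
  si <- scalability(ind, b4, "scale")
  expect_true(all(abs(si$item_h$h) < 0.05))

  # worked matrix (8 distinct patterns replicated to 24 persons) vs
  # exhaustive cov / comonotonic cov_max
  m <- matrix(c(0, 1, 2, 2, 0, 1, 0, 2,
                1, 1, 2, 0, 0, 2, 1, 2,
                0, 2, 2, 1, 1, 2, 0, 1), nrow = 8)
  m <- m[rep(1:8, 3), ]
  w <- tibble::tibble(person_id = sprintf("w%02d", 1:24))
  w[b3$item_id] <- as.data.frame(m)
  sw <- scalability(w, b3, "scale")
  for (r in seq_len(nrow(sw$pairwise_h))) {
    i <- match(sw$pairwise_h$item1[r], b3$item_id)
    j <- match(sw$pairwise_h$item2[r], b3$item_id)
    expect_equal(sw$pairwise_h$h[r],
                 cov(m[, i], m[, j]) / cov(sort(m[, i]), sort(m[, j])))
  }
  expect_true(all(sw$pairwise_h$h <= 1 + 1e-12))
})

test_that("rest-score traces are monotone for monotone data and flag reversals", {
  # deterministic monotone: item = thresholded rest score
  b3 <- generate_bank(3, seed = 15)
  score <- rep(0:4, each = 12)
  d <- tibble::tibble(person_id = sprintf("m%02d", seq_along(score)),
                      item01 = as.integer(pmin(score, 2)),
                      item02 = as.integer(pmin(pmax(score - 1, 0), 2)),
                      item03 = as.integer(pmin(pmax(score - 2, 0), 2)))
  tr <- rest_score_traces(d, b3, "scale", "item01", min_group = 5)
  expect_equal(tr$n_violations, 0)
  expect_true(all(tr$trace$n >= 5 | nrow(tr$trace) == 1))

  # anti-monotone constructed item
  d2 <- d
  d2$item01 <- 2L - d2$item01
  tr2 <- rest_score_traces(d2, b3, "scale", "item01", min_group = 5)
  expect_gte(tr2$n_violations, 1)
})

test_that("GRM-simulated data shows (almost) no manifest monotonicity violations", {
  # bins of at least n/10 persons (the conventional minimum group size for
  # manifest-monotonicity checks) keep binomial noise below the true
  # between-bin increments
  rm <- simulate_responses(dis_bank, withr::with_seed(16, rnorm(5000)),
                           seed = 16)
  viol <- vapply(dis_bank$item_id, function(id) {
    rest_score_traces(rm, dis_bank, "distress", id, min_group = 500)$n_violations
  }, numeric(1))
  expect_gte(mean(viol == 0), 0.95)
})
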