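test_that("boundary and category probabilities follow the closed form", {
  i33 <- fb[fb$item_id == "dep33", ]
  i35 <- fb[fb$item_id == "dep35", ]

  expect_equal(boundary_prob(i33, 1, 0.688), 0.5)
  expect_equal(boundary_prob(i33, 1, 50), 1, tolerance = 1e-12)
  expect_equal(boundary_prob(i33, 1, -50), 0, tolerance = 1e-12)
  # hand evaluation of the logistic form
  expect_equal(boundary_prob(i35, 2, 0), 1 / (1 + exp(2.457 * 0.828)))

  th <- seq(-4, 4, length.out = 33)
  p <- category_probs(i35, th)
  expect_equal(rowSums(p), rep(1, 33), tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_gt(category_probs(i33, -10)[, "p0"], 0.999)

  # the two depression items have different modal categories at high trait:
  # the narrow-threshold item peaks on "sometimes", the wide one on 2
  expect_equal(which.max(category_probs(i33, 1.0)), 2)
  expect_equal(which.max(category_probs(i35, 2.0)), 3)
})

test_that("derivative of the boundary curve matches a numeric derivative", {
  item <- list(alpha = 2.3, beta1 = -0.4, beta2 = 0.9)
  h <- 1e-6
  for (th in c(-2, 0, 1.5)) {
    for (k in 1:2) {
      pstar <- boundary_prob(item, k, th)
      analytic <- item$alpha * pstar * (1 - pstar)
      numeric <- (boundary_prob(item, k, th + h) -
                    boundary_prob(item, k, th - h)) / (2 * h)
      expect_equal(analytic, numeric, tolerance = 1e-6)
    }
  }
})

test_that("item information matches the numeric expected second derivative", {
  items <- list(
    fb[fb$item_id == "dep33", ],
    fb[fb$item_id == "dep35", ],
    list(alpha = 1.2, beta1 = -1, beta2 = 0.3)
  )
  h <- 1e-4
  for (item in items) {
    for (th in seq(-3, 3, by = 0.75)) {
      info <- item_information(item, th)
      expect_gte(info, 0)
      p <- category_probs(item, th)
      d2 <- vapply(1:3, function(k) {
        (log(category_probs(item, th + h)[, k]) -
           2 * log(p[, k]) +
           log(category_probs(item, th - h)[, k])) / h^2
      }, numeric(1))
      oracle <- -sum(p * d2)
      expect_equal(info, oracle, tolerance = 1e-5 * max(1, abs(oracle)))
    }
  }
})

test_that("information vanishes as alpha approaches zero and grows with alpha", {
  weak <- list(alpha = 1e-6, beta1 = 0, beta2 = 1)
  expect_lt(max(item_information(weak, seq(-6, 6, 0.5))), 1e-11)

  base <- list(alpha = 1.5, beta1 = -0.5, beta2 = 0.7)
  strong <- list(alpha = 3.0, beta1 = -0.5, beta2 = 0.7)
  grid <- seq(-4, 4, 0.05)
  expect_gt(max(item_information(strong, grid)), max(item_information(base, grid)))
})

test_that("test information is additive and doubling a bank halves SE^2", {
  a <- small_bank[1:3, ]
  b <- small_bank[4:6, ]
  th <- c(-1, 0, 1)
  expect_equal(test_information(small_bank, th),
               test_information(a, th) + test_information(b, th))
  expect_equal(test_information(small_bank[2, ], th),
               item_information(small_bank[2, ], th))

  info <- test_information(a, 0)
  expect_equal(se_from_information(2 * info)^2, se_from_information(info)^2 / 2)
  expect_identical(se_from_information(0), Inf)
})

test_that("CRC tables sum to one and anomaly detection matches a fine-grid scan", {
  wide <- list(alpha = 2, beta1 = -1.5, beta2 = 1.5, item_id = "wide")
  narrow <- list(alpha = 1, beta1 = 0, beta2 = 0.05, item_id = "narrow")
  tab <- crc_table(wide, seq(-4, 4, 0.1))
  sums <- tapply(tab$prob, tab$theta, sum)
  expect_equal(unname(as.vector(sums)), rep(1, length(unique(tab$theta))),
               tolerance = 1e-12)

  expect_false(detect_crc_anomaly(wide))
  expect_true(detect_crc_anomaly(narrow))
  # middle category is modal at the threshold midpoint for wide spacing
  mid <- category_probs(wide, (wide$beta1 + wide$beta2) / 2)
  expect_equal(which.max(mid), 2)

  # agreement with an exhaustive very fine scan
  for (item in list(wide, narrow, fb[fb$item_id == "dep33", ])) {
    fine <- seq(-5, 5, by = 0.001)
    modal2 <- any(max.col(category_probs(item, fine)) == 2)
    expect_identical(detect_crc_anomaly(item), !modal2)
  }
})

test_that("MML calibration recovers parameters and is EM-monotone", {
  rm <- simulate_responses(dep_bank, rnorm(1500), seed = 21)
  fit <- fit_grm_mml(rm, dep_bank, "depression", standard_errors = TRUE)
  expect_true(fit$converged)
  # log-likelihood never decreases across EM iterations
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_gt(cor(fit$bank$alpha, dep_bank$alpha), 0.9)
  ok <- dep_bank$alpha <= 4
  expect_lt(sqrt(mean((fit$bank$beta1 - dep_bank$beta1)[ok]^2)), 0.15)
  expect_lt(sqrt(mean((fit$bank$beta2 - dep_bank$beta2)[ok]^2)), 0.15)
  expect_true(all(is.finite(fit$bank$se_beta1)))
  expect_true(all(fit$bank$se_beta1 > 0))

  # person permutation leaves the calibration unchanged
  fit2 <- fit_grm_mml(rm[rev(seq_len(nrow(rm))), ], dep_bank, "depression",
                      standard_errors = FALSE)
  # summation order differs, so the EM stops at a minutely different point
  expect_equal(fit2$bank$alpha, fit$bank$alpha, tolerance = 1e-3)

  td <- tidy(fit)
  expect_equal(nrow(td), 6 * 3)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
})

test_that("tiny samples either converge within bounds or fail loudly", {
  rm <- simulate_responses(dep_bank, rnorm(50), seed = 22)
  res <- tryCatch(fit_grm_mml(rm, dep_bank, "depression",
                              standard_errors = FALSE),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "converge")
  } else {
    expect_true(all(res$bank$alpha > 0 & res$bank$alpha < 50))
  }
})

test_that("an unobserved category yields a flagged 2-category calibration", {
  bank <- generate_bank(3, seed = 23)
  rm <- simulate_responses(bank, rnorm(400), seed = 24)
  rm$item02[rm$item02 == 2L] <- 1L  # censor the top category
  expect_warning(fit <- fit_grm_mml(rm, bank, "scale",
                                    standard_errors = FALSE),
                 "item02")
  expect_true(fit$bank$degenerate[fit$bank$item_id == "item02"])
  expect_false(any(fit$bank$degenerate[fit$bank$item_id != "item02"]))
  expect_true(all(fit$bank$beta1 < fit$bank$beta2))
})
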