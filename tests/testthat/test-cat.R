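test_that("EAP with no items returns the prior", {
  est <- eap(dep_bank, integer(0))
  expect_equal(est$theta, 0)
  expect_equal(est$se, 1)
  expect_equal(est$n_items, 0L)
  est2 <- eap(dep_bank, integer(0), prior_mean = 0.5, prior_sd = 2)
  expect_equal(est2$theta, 0.5)
  expect_equal(est2$se, 2)
})

test_that("EAP orders trait estimates by response severity", {
  all2 <- setNames(rep(2L, 6), dep_bank$item_id)
  all0 <- setNames(rep(0L, 6), dep_bank$item_id)
  expect_gt(eap(dep_bank, all2)$theta, 0)
  expect_lt(eap(dep_bank, all0)$theta, 0)
  expect_error(eap(dep_bank, c(bogus = 1L)), "item ids")
  expect_error(eap(dep_bank, setNames(3L, "dep33")), "0, 1 or 2")
})

test_that("EAP matches dense fine-grid quadrature for random patterns", {
  withr::with_seed(41, {
    worst <- 0
    for (i in 1:100) {
      x <- setNames(sample(0:2, 6, replace = TRUE), dep_bank$item_id)
      est <- eap(dep_bank, x)
      nodes <- seq(-6, 6, length.out = 2001)
      w <- dnorm(nodes); w <- w / sum(w)
      ll <- rep(0, 2001)
      for (j in 1:6) {
        ll <- ll + log(category_probs(dep_bank[j, ], nodes)[, x[j] + 1])
      }
      post <- w * exp(ll - max(ll)); post <- post / sum(post)
      worst <- max(worst, abs(sum(post * nodes) - est$theta))
    }
    expect_lt(worst, 1e-3)
  })
})

test_that("eap_scores agrees with per-person eap", {
  rm <- simulate_responses(dep_bank, rnorm(20), seed = 42)
  scores <- eap_scores(rm, dep_bank)
  for (i in c(1, 7, 20)) {
    x <- setNames(as.integer(rm[i, dep_bank$item_id]), dep_bank$item_id)
    expect_equal(scores$theta[i], eap(dep_bank, x)$theta, tolerance = 1e-12)
    expect_equal(scores$se[i], eap(dep_bank, x)$se, tolerance = 1e-12)
  }
})

test_that("select_next is the exhaustive information argmax with a stable tie rule", {
  expect_identical(select_next(small_bank, "item04", 0), "item04")
  withr::with_seed(43, {
    for (i in 1:200) {
      bank <- generate_bank(sample(3:10, 1), seed = sample.int(1e6, 1))
      theta <- runif(1, -3, 3)
      avail <- sample(bank$item_id, sample(2:nrow(bank), 1))
      pick <- select_next(bank, avail, theta)
      avail_bank_order <- bank$item_id[sort(match(avail, bank$item_id))]
      infos <- vapply(avail_bank_order, function(id) {
        item_information(bank[bank$item_id == id, ], theta)
      }, numeric(1))
      expect_identical(pick, avail_bank_order[which.max(infos)])
    }
  })
  # two identical items: the lower-indexed wins
  twin <- item_bank(tibble::tibble(item_id = c("a", "b"), scale = "s",
                                   alpha = 2, beta1 = 0, beta2 = 1))
  expect_identical(select_next(twin, c("b", "a"), 0.3), "a")
  expect_error(select_next(twin, character(0), 0), "empty")
})

test_that("run_cat honours the stopping rules and their order", {
  rec <- record_for(small_bank, 0.3, seed = 44)

  one <- run_cat(small_bank, rec, stop_se = Inf)
  expect_equal(one$n_items, 1)
  expect_identical(one$stop_reason, "se_met")  # SE rule checked before cap

  all_items <- run_cat(small_bank, rec, stop_se = 0)
  expect_equal(all_items$n_items, nrow(small_bank))
  expect_identical(all_items$stop_reason, "pool_exhausted")
  expect_false(anyDuplicated(all_items$trace$item_id) > 0)

  capped <- run_cat(small_bank, rec, stop_se = 0, max_items = 3)
  expect_equal(capped$n_items, 3)
  expect_identical(capped$stop_reason, "max_items")

  expect_error(run_cat(small_bank, rec[-1], stop_se = 0.4), "cover")
})

test_that("post-hoc CAT is deterministic and dominated by the SE threshold", {
  recs <- simulate_responses(small_bank, rnorm(15), seed = 45)
  for (i in 1:5) {
    rec <- setNames(as.integer(recs[i, small_bank$item_id]),
                    small_bank$item_id)
    a <- run_cat(small_bank, rec, stop_se = 0.45)
    b <- run_cat(small_bank, rec, stop_se = 0.45)
    expect_identical(a$trace, b$trace)
    tighter <- run_cat(small_bank, rec, stop_se = 0.3)
    expect_gte(tighter$n_items, a$n_items)
    # SE trace is non-increasing (post-hoc, informative items first)
    expect_true(all(diff(a$trace$se) <= 0.05))
  }
})

test_that("the CAT trace equals a naive fine-grid re-implementation", {
  naive_cat <- function(bank, x, stop_se) {
    nodes <- seq(-6, 6, length.out = 2001)
    w <- dnorm(nodes); w <- w / sum(w)
    avail <- seq_len(nrow(bank))
    administered <- character(0)
    ll <- rep(0, 2001)
    theta <- 0
    repeat {
      infos <- vapply(avail, function(j) {
        item_information(bank[j, ], theta)
      }, numeric(1))
      pick <- avail[which.max(infos)]
      avail <- setdiff(avail, pick)
      administered <- c(administered, bank$item_id[pick])
      ll <- ll + log(category_probs(bank[pick, ], nodes)[, x[bank$item_id[pick]] + 1])
      post <- w * exp(ll - max(ll)); post <- post / sum(post)
      theta <- sum(post * nodes)
      se <- sqrt(sum(post * (nodes - theta)^2))
      if (se <= stop_se || length(avail) == 0) break
    }
    administered
  }
  recs <- simulate_responses(dep_bank, rnorm(50), seed = 46)
  for (i in seq_len(50)) {
    x <- setNames(as.integer(recs[i, dep_bank$item_id]), dep_bank$item_id)
    mine <- run_cat(dep_bank, x, stop_se = 0.4)
    expect_identical(mine$trace$item_id, naive_cat(dep_bank, x, 0.4))
  }
})

test_that("stop_se = 0 reproduces the full test exactly", {
  rm <- simulate_responses(small_bank, rnorm(40), seed = 47)
  sim <- simulate_cat(small_bank, rm, stop_se = 0)
  expect_equal(sim$summary$mean_items, nrow(small_bank))
  expect_identical(sim$summary$correlation, 1)
  # bit-for-bit equality with the direct full-bank EAP
  full <- eap_scores(rm, small_bank)
  expect_identical(sim$persons$theta_cat, sim$persons$theta_full)
  expect_equal(sim$persons$theta_cat, full$theta, tolerance = 1e-12)
})

test_that("efficiency tables are monotone in the stopping threshold", {
  rm <- simulate_responses(dep_bank, rnorm(60), seed = 48)
  tab <- se_grid(dep_bank, rm, grid = c(0.3, 0.45, 0.6, 0.8))
  expect_equal(nrow(tab), 4)
  expect_true(all(diff(tab$mean_items) <= 0))
  expect_true(all(diff(tab$correlation) <= 0.02))
  expect_error(se_grid(dep_bank, rm, grid = c(0.5, 0.3)), "ascending")

  capped <- simulate_cat(dep_bank, rm, stop_se = 1e-9, max_items = 3)
  expect_true(all(capped$persons$n_items == 3))
  expect_equal(capped$summary$sd_items, 0)
})

test_that("the full-scale reference SE is a grid member rounded up", {
  rm <- simulate_responses(dep_bank, rnorm(80), seed = 49)
  suppressMessages({
    ref <- full_scale_reference_se(dep_bank, rm)
  })
  grid <- seq(0.2, 0.8, by = 0.1)
  expect_true(as.numeric(ref) %in% grid)
  expect_gte(as.numeric(ref), attr(ref, "unrounded"))
  expect_lt(as.numeric(ref) - attr(ref, "unrounded"), 0.1)

  # a bank with enormous information saturates at the smallest grid value
  huge <- item_bank(tibble::tibble(
    item_id = sprintf("h%02d", 1:16), scale = "s",
    alpha = 50, beta1 = seq(-3, 2.6, length.out = 16),
    beta2 = seq(-3, 2.6, length.out = 16) + 1
  ))
  rm_h <- simulate_responses(huge, rnorm(50), seed = 50)
  suppressMessages(ref_h <- full_scale_reference_se(huge, rm_h))
  expect_equal(as.numeric(ref_h), 0.2)
})

test_that("caps alone give the half-length arithmetic", {
  # unreachable precision + half-length caps over the four scales:
  # 8 + 3 + 6 + 8 = 25 of 50 items, a 50% reduction
  caps <- c(distress = 8, depression = 3, anxiety = 6, somatization = 8)
  lens <- c(distress = 16, depression = 6, anxiety = 12, somatization = 16)
  red <- reduction_summary(caps, lens)
  expect_equal(red$total_items, 25)
  expect_equal(red$reduction_pct, 50)

  cohort <- generate_cohort(fb, n = 30, seed = 51)
  mean_items <- vapply(names(lens), function(sc) {
    b <- fb[fb$scale == sc, ]
    rm <- cohort$responses[c("person_id", b$item_id)]
    simulate_cat(b, rm, stop_se = 1e-9,
                 max_items = lens[[sc]] / 2)$summary$mean_items
  }, numeric(1))
  expect_equal(unname(mean_items), unname(caps))
})
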