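# Shared fixtures, all generated in code.

fb <- fixture_bank()
dep_bank <- fb[fb$scale == "depression", ]
dis_bank <- fb[fb$scale == "distress", ]

# a small generic single-scale bank for cheap tests
small_bank <- generate_bank(6, seed = 42)

# named response record for one person covering a bank
record_for <- function(bank, theta, seed = 1) {
  resp <- simulate_responses(bank, theta, seed = seed)
  setNames(as.integer(resp[1, bank$item_id]), bank$item_id)
}

# simulate two items whose latent inputs share an extra factor beyond the
# common trait (for local-dependence tests): the effective trait of the
# flagged pair is (theta + lambda u)/sqrt(1 + lambda^2), u shared.
simulate_correlated_error_pair <- function(bank, pair, lambda, n, seed) {
  withr::with_seed(seed, {
    theta <- rnorm(n)
    u <- rnorm(n)
    th_eff <- matrix(theta, n, nrow(bank))
    colnames(th_eff) <- bank$item_id
    for (id in pair) {
      th_eff[, id] <- (theta + lambda * u) / sqrt(1 + lambda^2)
    }
    cols <- lapply(seq_len(nrow(bank)), function(j) {
      p <- category_probs(bank[j, ], th_eff[, j])
      uu <- runif(n)
      as.integer((uu > p[, 1]) + (uu > p[, 1] + p[, 2]))
    })
    out <- tibble::tibble(person_id = sprintf("p%04d", seq_len(n)))
    out[bank$item_id] <- cols
    out
  })
}
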