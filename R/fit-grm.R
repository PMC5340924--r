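# Marginal maximum likelihood calibration of the graded response model by
# an EM algorithm with fixed normal quadrature.
#
# E-step: posterior weights of each person over the theta grid under the
# current item parameters. M-step: per item, maximize the expected
# complete-data log-likelihood sum_q sum_k r_qk log P_k(theta_q), where the
# expected counts r_qk depend on the data only through a Q x 3 table, so
# the M-step cost is independent of sample size.

quad_nodes <- function(quad_points = 61, prior_mean = 0, prior_sd = 1,
                       span = 4.5) {
  nodes <- prior_mean + prior_sd * seq(-span, span, length.out = quad_points)
  w <- dnorm(nodes, prior_mean, prior_sd)
  list(nodes = nodes, weights = w / sum(w))
}

# Q x 3 log category probabilities for one item at the grid, honouring the
# item's category pattern ("full", or collapsed 2-category variants).
item_log_probs <- function(par, nodes, type = "full") {
  if (type == "full") {
    p <- category_probs(list(alpha = par[1], beta1 = par[2], beta2 = par[3]),
                        nodes)
  } else {
    pstar <- plogis(par[1] * (nodes - par[2]))
    p <- switch(type,
      no2 = cbind(1 - pstar, pstar, 0),
      no0 = cbind(0, 1 - pstar, pstar),
      no1 = cbind(1 - pstar, 0, pstar)
    )
  }
  log(pmax(p, 1e-300))
}

# bounded natural <-> unconstrained parameterizations
# alpha in (0.05, 50) via logistic; beta1 in (-10, 10) via tanh;
# beta2 = beta1 + exp(delta)
to_unconstrained <- function(alpha, beta1, spacing) {
  c(qlogis(pmin(pmax((alpha - 0.05) / 49.95, 1e-8), 1 - 1e-8)),
    atanh(pmin(pmax(beta1 / 10, -1 + 1e-8), 1 - 1e-8)),
    log(pmax(spacing, 1e-6)))
}

from_unconstrained <- function(u) {
  alpha <- 0.05 + 49.95 * plogis(u[1])
  beta1 <- 10 * tanh(u[2])
  c(alpha, beta1, beta1 + exp(u[3]))
}

item_category_type <- function(x) {
  present <- sort(unique(x))
  if (identical(present, 0:2)) return("full")
  if (length(present) < 2) {
    abort("item with a single observed category cannot be calibrated")
  }
  if (identical(present, 0:1)) "no2" else if (identical(present, 1:2)) "no0" else "no1"
}

mstep_item <- function(r_qk, nodes, type, par0) {
  if (type == "full") {
    obj <- function(u) {
      par <- from_unconstrained(u)
      -sum(r_qk * item_log_probs(par, nodes, "full"))
    }
    u0 <- to_unconstrained(par0[1], par0[2], par0[3] - par0[2])
    opt <- optim(u0, obj, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-10))
    from_unconstrained(opt$par)
  } else {
    # single boundary: alpha in (0.05, 50), location in (-10, 10)
    obj <- function(u) {
      par <- c(0.05 + 49.95 * plogis(u[1]), 10 * tanh(u[2]))
      -sum(r_qk * item_log_probs(par, nodes, type))
    }
    u0 <- c(qlogis(pmin(pmax((par0[1] - 0.05) / 49.95, 1e-8), 1 - 1e-8)),
            atanh(pmin(pmax(par0[2] / 10, -1 + 1e-8), 1 - 1e-8)))
    opt <- optim(u0, obj, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-10))
    c(0.05 + 49.95 * plogis(opt$par[1]), 10 * tanh(opt$par[2]), NA)
  }
}

# expand a (possibly collapsed) parameter vector to a bank row
expand_pars <- function(par, type) {
  switch(type,
    full = c(alpha = par[1], beta1 = par[2], beta2 = par[3]),
    no2 = c(alpha = par[1], beta1 = par[2], beta2 = par[2] + 4),
    no0 = c(alpha = par[1], beta1 = par[2] - 4, beta2 = par[2]),
    no1 = c(alpha = par[1], beta1 = par[2] - 0.005, beta2 = par[2] + 0.005)
  )
}

#' Calibrate a scale with the graded response model (marginal ML)
#'
#' Fits Samejima's GRM (logistic metric, no 1.7 scaling constant) to one
#' scale's 0/1/2 responses by marginal maximum likelihood: an EM algorithm
#' integrating the latent trait over a fixed standard-normal quadrature
#' grid. Discriminations are bounded in (0.05, 50) and thresholds in
#' (-10, 10) through smooth reparameterization; threshold ordering is
#' enforced by estimating the log spacing. Items with an unobserved
#' response category are calibrated as two-category items and flagged
#' (`degenerate = TRUE`); their missing threshold is imputed outside the
#' observable range so the returned bank stays valid.
#'
#' @inheritParams scale_totals
#' @param quad_points Number of quadrature nodes on \[-4.5, 4.5\].
#' @param max_iter EM iteration cap.
#' @param tol Convergence tolerance on the maximum absolute parameter change.
#' @param standard_errors Compute per-item observed-information standard
#'   errors (numerical Hessian of the marginal likelihood, other items
#'   fixed)? Default `TRUE`.
#' @param nonconvergence `"error"` (default) aborts with the iteration
#'   trace when `max_iter` is reached; `"warn"` returns the last iterate
#'   with `converged = FALSE`.
#' @return An object of class `grm_fit`: `bank` (item tibble with
#'   parameters, standard errors and a `degenerate` flag), `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `n`.
#' @examples
#' bank <- generate_bank(5, seed = 1)
#' rm <- simulate_responses(bank, rnorm(300), seed = 2)
#' fit <- fit_grm_mml(rm, bank, "scale", standard_errors = FALSE)
#' tidy(fit)
#' @export
fit_grm_mml <- function(responses, bank, scale, quad_points = 61,
                        max_iter = 500, tol = 1e-5,
                        standard_errors = TRUE,
                        nonconvergence = c("error", "warn")) {
  nonconvergence <- match.arg(nonconvergence)
  items <- scale_items(bank, scale)
  if (length(items) < 2) abort("GRM calibration needs >= 2 items")
  m <- response_matrix(responses, items)
  if (anyNA(m)) abort("GRM calibration requires complete cases")
  n <- nrow(m)
  J <- ncol(m)
  q <- quad_nodes(quad_points)
  types <- apply(m, 2, item_category_type)
  if (any(types != "full")) {
    warn(paste0("item(s) with an unobserved category calibrated as ",
                "2-category: ", paste(items[types != "full"], collapse = ", ")))
  }

  # starting values from marginal category proportions at alpha = 1.5
  pars <- matrix(NA_real_, J, 3)
  for (j in seq_len(J)) {
    a0 <- 1.5
    p1 <- min(max(mean(m[, j] >= 1), 0.01), 0.99)
    p2 <- min(max(mean(m[, j] >= 2), 0.01), 0.99)
    b1 <- -qlogis(p1) / a0
    b2 <- max(-qlogis(p2) / a0, b1 + 0.2)
    pars[j, ] <- if (types[j] == "full") c(a0, b1, b2) else
      c(a0, if (types[j] == "no0") b2 else b1, NA)
  }

  ind <- lapply(seq_len(J), function(j) {
    cbind(m[, j] == 0, m[, j] == 1, m[, j] == 2) * 1
  })

  loglik_trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    logp <- lapply(seq_len(J), function(j) item_log_probs(pars[j, ], q$nodes, types[j]))
    logL <- matrix(0, n, quad_points)
    for (j in seq_len(J)) logL <- logL + t(logp[[j]][, m[, j] + 1])
    a <- sweep(logL, 2, log(q$weights), `+`)
    amax <- apply(a, 1, max)
    post <- exp(a - amax)
    norm <- rowSums(post)
    post <- post / norm
    loglik_trace <- c(loglik_trace, sum(log(norm) + amax))

    new_pars <- pars
    for (j in seq_len(J)) {
      r_qk <- crossprod(post, ind[[j]])  # Q x 3 expected counts
      new_pars[j, ] <- mstep_item(r_qk, q$nodes, types[j], pars[j, ])
    }
    delta <- max(abs(new_pars - pars), na.rm = TRUE)
    pars <- new_pars
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    msg <- paste0("GRM EM did not converge in ", max_iter,
                  " iterations (last max parameter change ",
                  format(delta, digits = 3), "; log-likelihood trace tail: ",
                  paste(round(tail(loglik_trace, 3), 4), collapse = ", "), ")")
    if (nonconvergence == "error") abort(msg) else warn(msg)
  }

  full_pars <- t(vapply(seq_len(J), function(j) expand_pars(pars[j, ], types[j]),
                        numeric(3)))
  out_bank <- tibble(
    item_id = items, scale = scale,
    alpha = full_pars[, 1], beta1 = full_pars[, 2], beta2 = full_pars[, 3],
    se_alpha = NA_real_, se_beta1 = NA_real_, se_beta2 = NA_real_,
    degenerate = types != "full"
  )

  if (standard_errors) {
    logp <- lapply(seq_len(J), function(j) item_log_probs(pars[j, ], q$nodes, types[j]))
    contrib <- lapply(seq_len(J), function(j) t(logp[[j]][, m[, j] + 1]))
    total <- Reduce(`+`, contrib)
    for (j in seq_len(J)) {
      if (types[j] != "full") next
      base <- total - contrib[[j]]
      f <- function(par) {
        lj <- t(item_log_probs(par, q$nodes, "full")[, m[, j] + 1])
        a <- sweep(base + lj, 2, log(q$weights), `+`)
        amax <- apply(a, 1, max)
        sum(log(rowSums(exp(a - amax))) + amax)
      }
      h <- tryCatch(pracma::hessian(f, pars[j, ]), error = function(e) NULL)
      se <- tryCatch(sqrt(diag(solve(-h))), error = function(e) rep(NA_real_, 3))
      if (!is.null(h) && length(se) == 3) {
        out_bank$se_alpha[j] <- se[1]
        out_bank$se_beta1[j] <- se[2]
        out_bank$se_beta2[j] <- se[3]
      }
    }
  }

  structure(list(
    bank = out_bank, loglik = tail(loglik_trace, 1),
    loglik_trace = loglik_trace, n_iter = iter, converged = converged,
    n = n, quad_points = quad_points, tol = tol
  ), class = "grm_fit")
}

#' @export
print.grm_fit <- function(x, ...) {
  cat("GRM marginal ML fit: ", nrow(x$bank), " items, n = ", x$n,
      ", ", x$n_iter, " EM iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(x$bank)
  invisible(x)
}

#' @method tidy grm_fit
#' @export
tidy.grm_fit <- function(x, ...) {
  x$bank |>
    tidyr::pivot_longer(c("alpha", "beta1", "beta2"),
                        names_to = "term", values_to = "estimate") |>
    dplyr::mutate(std.error = dplyr::case_when(
      .data$term == "alpha" ~ .data$se_alpha,
      .data$term == "beta1" ~ .data$se_beta1,
      TRUE ~ .data$se_beta2
    )) |>
    dplyr::select("item_id", "scale", "term", "estimate", "std.error",
                  "degenerate")
}

#' @method glance grm_fit
#' @export
glance.grm_fit <- function(x, ...) {
  tibble(n = x$n, n_items = nrow(x$bank), logLik = x$loglik,
         n_iter = x$n_iter, converged = x$converged,
         n_degenerate = sum(x$bank$degenerate))
}

#' @method autoplot grm_fit
#' @export
autoplot.grm_fit <- function(object, theta_grid = seq(-4, 4, 0.05), ...) {
  tabs <- purrr::map_dfr(seq_len(nrow(object$bank)), function(j) {
    crc_table(object$bank[j, ], theta_grid)
  })
  autoplot.crc_table(tabs)
}
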