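# Bivariate normal CDF and two-step polychoric correlation estimation.
# The bivariate CDF is reduced to a 1-D integral,
#   Phi2(a, b, rho) = int_{-inf}^{a} phi(x) Phi((b - rho x)/sqrt(1-rho^2)) dx,
# evaluated by fixed Gauss-Legendre quadrature on [-8, a].

.quad_cache <- new.env(parent = emptyenv())

gl_nodes <- function(n = 64) {
  key <- as.character(n)
  if (is.null(.quad_cache[[key]])) {
    .quad_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  .quad_cache[[key]]
}

#' Bivariate standard normal CDF
#'
#' \eqn{P(X \le a, Y \le b)} for standard normal margins with correlation
#' `rho`, by Gauss-Legendre quadrature of the conditional-probability
#' integral. Vectorized over `a` and `b`.
#'
#' @param a,b Upper limits (may be `Inf` / `-Inf`).
#' @param rho Correlation in (-1, 1).
#' @param n_nodes Quadrature nodes (default 64).
#' @return Numeric vector of probabilities.
#' @export
pbinorm <- function(a, b, rho, n_nodes = 64) {
  stopifnot(abs(rho) < 1)
  k <- max(length(a), length(b))
  a <- rep_len(a, k)
  b <- rep_len(b, k)
  out <- numeric(k)
  s <- sqrt(1 - rho^2)
  gl <- gl_nodes(n_nodes)
  for (i in seq_len(k)) {
    if (a[i] == -Inf || b[i] == -Inf) {
      out[i] <- 0
    } else if (a[i] == Inf) {
      out[i] <- pnorm(b[i])
    } else if (b[i] == Inf) {
      out[i] <- pnorm(a[i])
    } else {
      lo <- -8
      hi <- min(a[i], 8)
      if (hi <= lo) {
        out[i] <- 0
      } else {
        x <- lo + (hi - lo) * gl$x
        w <- (hi - lo) * gl$w
        out[i] <- sum(w * dnorm(x) * pnorm((b[i] - rho * x) / s))
      }
    }
  }
  out
}

# Interior normal thresholds from the marginal distribution of an ordinal
# variable; categories with zero cumulative mass at either end are dropped.
marginal_thresholds <- function(x) {
  tab <- table(factor(x))
  p <- cumsum(tab) / sum(tab)
  cuts <- p[-length(p)]
  qnorm(cuts[cuts > 0 & cuts < 1])
}

# Cell probabilities of the discretized bivariate normal at correlation rho.
binorm_cellprobs <- function(rho, ta, tb) {
  a <- c(-Inf, ta, Inf)
  b <- c(-Inf, tb, Inf)
  cum <- outer(a, b, function(ai, bj) pbinorm(ai, bj, rho))
  nr <- length(a)
  nc <- length(b)
  cum[2:nr, 2:nc] - cum[1:(nr - 1), 2:nc] -
    cum[2:nr, 1:(nc - 1)] + cum[1:(nr - 1), 1:(nc - 1)]
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum likelihood: normal thresholds are fixed at the
#' quantiles of each margin, then the latent correlation is found by a
#' bounded 1-D likelihood search on (-0.999, 0.999).
#'
#' @param x,y Integer ordinal vectors of equal length (complete cases).
#' @return Estimated latent correlation.
#' @export
polychoric_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("polychoric correlation needs >= 2 observed categories per variable")
  }
  counts <- table(factor(x), factor(y))
  ta <- marginal_thresholds(x)
  tb <- marginal_thresholds(y)
  negll <- function(rho) {
    p <- binorm_cellprobs(rho, ta, tb)
    -sum(counts * log(pmax(p, 1e-12)))
  }
  optimize(negll, interval = c(-0.999, 0.999), tol = 1e-6)$minimum
}

#' Polychoric correlation matrix of a scale
#'
#' Pairwise two-step polychoric correlations among one scale's items, the
#' standard substrate for an ordinal confirmatory factor analysis.
#'
#' @inheritParams scale_totals
#' @return Symmetric correlation matrix with unit diagonal, dimnames the
#'   item ids.
#' @examples
#' bank <- generate_bank(4, seed = 1)
#' rm <- simulate_responses(bank, rnorm(200), seed = 2)
#' polychoric_matrix(rm, bank, "scale")
#' @export
polychoric_matrix <- function(responses, bank, scale) {
  items <- scale_items(bank, scale)
  if (length(items) < 2) abort("polychoric matrix needs >= 2 items")
  m <- response_matrix(responses, items)
  degenerate <- items[apply(m, 2, function(v) length(unique(v[!is.na(v)])) < 2)]
  if (length(degenerate) > 0) {
    abort(paste0("item(s) with a single observed category: ",
                 paste(degenerate, collapse = ", ")))
  }
  p <- length(items)
  r <- diag(1, p)
  dimnames(r) <- list(items, items)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r[i, j] <- r[j, i] <- polychoric_corr(m[, i], m[, j])
    }
  }
  r
}
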