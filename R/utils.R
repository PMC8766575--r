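# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' @noRd
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' @noRd
flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' @noRd
comp_base <- function(b) unname(COMPLEMENT[b])

#' Draw from a Beta distribution parameterized by mean and intraclass
#' correlation.  At rho below 1e-8 the distribution degenerates to a point
#' mass at mu.
#' @noRd
rbeta_mu_rho <- function(n, mu, rho) {
  stopifnot(all(mu >= 0 & mu <= 1), all(rho >= 0 & rho < 1))
  if (length(mu) == 1L) mu <- rep(mu, n)
  if (length(rho) == 1L) rho <- rep(rho, n)
  out <- mu
  live <- rho > 1e-8 & mu > 0 & mu < 1
  if (any(live)) {
    a <- mu[live] * (1 - rho[live]) / rho[live]
    b <- (1 - mu[live]) * (1 - rho[live]) / rho[live]
    out[live] <- stats::rbeta(sum(live), a, b)
  }
  out
}

#' Beta-binomial draw: per-unit probability from Beta(mu, rho), then a
#' binomial count of size `size`.
#' @noRd
rbetabinom <- function(n, size, mu, rho) {
  p <- rbeta_mu_rho(n, mu, rho)
  stats::rbinom(n, size, p)
}

#' Phred qualities (integer) from an ASCII+33 quality string.
#' @noRd
phred_ints <- function(qual_concat) utf8ToInt(qual_concat) - 33L

#' Substitute single characters inside a character vector at given
#' (element, offset) pairs.  Offsets are 1-based.
#' @noRd
substr_assign <- function(x, idx, offset, value) {
  for (j in seq_along(idx)) {
    substr(x[idx[j]], offset[j], offset[j]) <- value[j]
  }
  x
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
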