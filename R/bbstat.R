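#' Beta-binomial log-likelihood with logit mean model and shared dispersion
#'
#' The count k_i ~ BetaBinomial(n_i, a_i, b_i) with a_i = mu_i (1-rho)/rho,
#' b_i = (1-mu_i)(1-rho)/rho and mu_i = logistic(x_i' beta).  The intraclass
#' correlation rho lies in \[0, 1); as rho -> 0 the likelihood converges to
#' the binomial likelihood, and below 1e-8 the binomial limit is evaluated
#' directly (the Beta-function form loses precision there).
#'
#' @param k,n integer vectors of successes and trials.
#' @param X design matrix (rows match k).
#' @param beta coefficient vector on the logit-mean scale.
#' @param rho dispersion in \[0, 1).
#' @return total log-likelihood (scalar).
#' @export
bb_loglik <- function(k, n, X, beta, rho) {
  stopifnot(length(k) == length(n), nrow(X) == length(k),
            ncol(X) == length(beta))
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n")
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)")
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  if (rho < 1e-8)
    return(sum(stats::dbinom(k, n, mu, log = TRUE)))
  s <- (1 - rho) / rho
  a <- mu * s
  b <- (1 - mu) * s
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

#' Design matrix for condition + patient fixed effects
#'
#' Intercept, a tumor indicator, and patient indicator coding with the first
#' patient (alphabetically) as reference.
#' @noRd
bb_design <- function(condition, patient, with_condition = TRUE) {
  stopifnot(length(condition) == length(patient))
  pats <- sort(unique(as.character(patient)))
  X <- matrix(1, nrow = length(condition), ncol = 1,
              dimnames = list(NULL, "(Intercept)"))
  if (with_condition)
    X <- cbind(X, condition_tumor = as.numeric(condition == "tumor"))
  if (length(pats) > 1L) {
    P <- vapply(pats[-1L], function(p) as.numeric(patient == p),
                numeric(length(patient)))
    colnames(P) <- paste0("patient_", pats[-1L])
    X <- cbind(X, P)
  }
  X
}

#' Fit a beta-binomial regression by maximum likelihood
#'
#' Mean model: logit(mu) = intercept + condition + patient indicators;
#' one dispersion rho shared across all observations of the unit.  The
#' optimizer (BFGS on an unconstrained reparameterization, rho mapped into
#' \[1e-6, 1-1e-6\] through a scaled logistic) starts from beta = 0 except the
#' intercept at the logit of the pooled rate, and rho = 0.01, so the fit is
#' deterministic for given data.  Units in which every observation is all
#' successes or all failures return a flagged boundary fit instead of
#' failing.
#'
#' @param k,n successes and trials per observation.
#' @param condition character vector, "tumor" or "normal".
#' @param patient patient identifier per observation.
#' @param with_condition if FALSE, fit the reduced (patient-only) model.
#' @param rho if supplied, the dispersion is held fixed at this value and
#'   only the mean coefficients are optimized (used by the testing driver,
#'   which plugs in the Cox-Reid-adjusted estimate from
#'   [estimate_dispersion_cr()]).
#' @return list of class `bb_fit`: coefficients, rho, loglik, converged,
#'   degenerate, plus the data and design used.
#' @export
fit_bb_regression <- function(k, n, condition, patient,
                              with_condition = TRUE, rho = NULL) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]
  condition <- condition[keep]; patient <- as.character(patient)[keep]
  if (!length(k)) stop("no observations with positive trial counts")
  X <- bb_design(condition, patient, with_condition)
  lb <- 1e-6; ub <- 1 - 1e-6
  degenerate <- all(k == 0L) || all(k == n)

  if (degenerate) {
    # boundary of the mean scale: report the clamped pooled-rate fit
    p0 <- clamp(sum(k) / sum(n), 1e-9, 1 - 1e-9)
    beta <- c(stats::qlogis(p0), rep(0, ncol(X) - 1L))
    names(beta) <- colnames(X)
    ll <- bb_loglik(k, n, X, beta, rho %||% lb)
    return(structure(list(coefficients = beta, rho = rho %||% lb,
                          loglik = ll,
                          converged = TRUE, degenerate = TRUE,
                          k = k, n = n, X = X,
                          condition = condition, patient = patient),
                     class = "bb_fit"))
  }

  p0 <- (sum(k) + 0.5) / (sum(n) + 1)
  if (!is.null(rho)) {
    if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
    fx <- fit_bb_mean(k, n, X, rho, p0)
    return(structure(list(coefficients = fx$beta, rho = rho,
                          loglik = fx$ll, converged = fx$converged,
                          degenerate = FALSE, k = k, n = n, X = X,
                          condition = condition, patient = patient),
                     class = "bb_fit"))
  }

  rho_of <- function(phi) lb + (ub - lb) * stats::plogis(phi)
  start <- c(stats::qlogis(p0), rep(0, ncol(X) - 1L),
             stats::qlogis((0.01 - lb) / (ub - lb)))
  negll <- function(theta) {
    beta <- theta[seq_len(ncol(X))]
    rho <- rho_of(theta[length(theta)])
    ll <- bb_loglik(k, n, X, beta, rho)
    if (!is.finite(ll)) 1e12 else -ll
  }
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  beta <- opt$par[seq_len(ncol(X))]
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, rho = rho_of(opt$par[length(opt$par)]),
                 loglik = -opt$value, converged = opt$convergence == 0L,
                 degenerate = FALSE, k = k, n = n, X = X,
                 condition = condition, patient = patient),
            class = "bb_fit")
}

# mean-model fit at fixed dispersion, with an optional warm start
fit_bb_mean <- function(k, n, X, rho, p0, start = NULL) {
  if (is.null(start)) start <- c(stats::qlogis(p0), rep(0, ncol(X) - 1L))
  negll <- function(beta) {
    ll <- bb_loglik(k, n, X, beta, rho)
    if (!is.finite(ll)) 1e12 else -ll
  }
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  beta <- opt$par
  names(beta) <- colnames(X)
  list(beta = beta, ll = -opt$value, converged = opt$convergence == 0L)
}

#' Cox-Reid-adjusted dispersion estimate for one unit
#'
#' Maximizes the adjusted profile likelihood of the intraclass correlation
#' rho: the profile log-likelihood (mean coefficients maximized out at each
#' rho on the full condition + patient design) minus one half the log
#' determinant of the working Fisher information of the mean coefficients.
#' The adjustment compensates the downward bias of the plain maximum
#' likelihood estimate when many mean parameters (one per patient) share
#' few observations, which would otherwise make the likelihood-ratio test
#' anticonservative.
#'
#' @param k,n successes and trials per observation.
#' @param condition,patient design factors as in [fit_bb_regression()].
#' @return the dispersion estimate (scalar in \[1e-6, 0.9\]).
#' @export
estimate_dispersion_cr <- function(k, n, condition, patient) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]
  condition <- condition[keep]; patient <- as.character(patient)[keep]
  if (all(k == 0L) || all(k == n)) return(1e-6)
  X <- bb_design(condition, patient, TRUE)
  p0 <- (sum(k) + 0.5) / (sum(n) + 1)
  warm <- NULL
  apl <- function(lrho) {
    rho <- exp(lrho)
    fx <- fit_bb_mean(k, n, X, rho, p0, start = warm)
    warm <<- fx$beta
    mu <- stats::plogis(drop(X %*% fx$beta))
    w <- n * mu * (1 - mu) / (1 + (n - 1) * rho)
    info <- crossprod(X, X * w)
    ld <- determinant(info, logarithm = TRUE)$modulus
    fx$ll - 0.5 * as.numeric(ld)
  }
  opt <- stats::optimize(function(l) -apl(l), interval = log(c(1e-6, 0.9)))
  exp(opt$minimum)
}

#' Likelihood-ratio test for the condition effect
#'
#' @param full fit with the condition term.
#' @param reduced fit of the same data without the condition term.
#' @return list with `statistic` (2 * (ll_full - ll_reduced), clipped at 0)
#'   and `p_value` from a chi-square with 1 degree of freedom.
#' @export
lrt_condition <- function(full, reduced) {
  stopifnot(inherits(full, "bb_fit"), inherits(reduced, "bb_fit"))
  if (length(full$k) != length(reduced$k) ||
      any(full$k != reduced$k) || any(full$n != reduced$n))
    stop("'full' and 'reduced' were fitted on different data")
  if (ncol(full$X) != ncol(reduced$X) + 1L)
    stop("'reduced' must drop exactly the condition term")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotone enforcement, order-preserving.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential proportion test over many units
#'
#' For each unit (editing site or gene): estimates the shared dispersion by
#' the Cox-Reid-adjusted profile likelihood on the full design, fits the
#' full and reduced beta-binomial mean models at that dispersion, tests the
#' condition effect by likelihood ratio against a chi-square with one
#' degree of freedom, and adjusts p-values by Benjamini-Hochberg across
#' units.  Degenerate units (all-zero or all-n successes) are reported with
#' p = 1 rather than dropped.
#'
#' @param obs data.table with columns unit_id, sample_id, k, n, condition,
#'   patient_id.
#' @return data.table: unit_id, estimate (condition effect on the logit
#'   scale), rho, statistic, p_value, fdr_adjusted_p, mean_tumor,
#'   mean_normal, diff (tumor - normal mean observed proportion),
#'   degenerate, converged.
#' @export
bb_diff_test <- function(obs) {
  need <- c("unit_id", "k", "n", "condition", "patient_id")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(obs$k > obs$n)) stop("need k <= n for every observation")
  units <- unique(obs$unit_id)
  res <- lapply(units, function(u) {
    d <- obs[unit_id == u]
    dd <- d[n > 0]
    means <- dd[, .(m = mean(k / n)), by = condition]
    m_t <- means[condition == "tumor", m]
    m_n <- means[condition == "normal", m]
    m_t <- if (length(m_t)) m_t else NA_real_
    m_n <- if (length(m_n)) m_n else NA_real_
    degen <- nrow(dd) == 0L || all(dd$k == 0L) || all(dd$k == dd$n) ||
      data.table::uniqueN(dd$condition) < 2L
    if (degen) {
      return(data.table::data.table(
        unit_id = u, estimate = 0, rho = NA_real_, statistic = 0,
        p_value = 1, mean_tumor = m_t, mean_normal = m_n,
        diff = m_t - m_n, degenerate = TRUE, converged = TRUE))
    }
    rho_cr <- estimate_dispersion_cr(d$k, d$n, d$condition, d$patient_id)
    full <- fit_bb_regression(d$k, d$n, d$condition, d$patient_id,
                              rho = rho_cr)
    red <- fit_bb_regression(d$k, d$n, d$condition, d$patient_id,
                             with_condition = FALSE, rho = rho_cr)
    lrt <- lrt_condition(full, red)
    data.table::data.table(
      unit_id = u, estimate = unname(full$coefficients["condition_tumor"]),
      rho = rho_cr, statistic = lrt$statistic, p_value = lrt$p_value,
      mean_tumor = m_t, mean_normal = m_n, diff = m_t - m_n,
      degenerate = FALSE, converged = full$converged && red$converged)
  })
  out <- data.table::rbindlist(res)
  out[, fdr_adjusted_p := bh_adjust(p_value)]
  data.table::setcolorder(out, c("unit_id", "estimate", "rho", "statistic",
                                 "p_value", "fdr_adjusted_p"))
  out[]
}
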