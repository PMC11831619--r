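# Quantile-regression fitting for diagnostic-interval contrasts.
#
# The estimator minimizes the asymmetric absolute (check) loss
#   sum_i rho_tau(y_i - x_i' b),  rho_tau(u) = u * (tau - 1[u < 0]),
# solved exactly as a linear program (simplex, via quantreg's
# Barrodale-Roberts routine). Because check-loss minimizers are set-valued
# when a subgroup count times tau is an integer, the fit is run at a tau
# perturbed downward by delta = min(tau, 1 - tau) * 1e-3 / n. The
# perturbation is small enough never to cross a quantile breakpoint (n *
# delta < 1/q for any tau = p/q with q <= 1000, for every subgroup size), yet
# large enough to break vertex ties toward the lower vertex of the optimal
# set; on factor-only designs this makes coefficients reproduce
# lower-interpolation (type 1) sample quantiles exactly, so unadjusted
# median-regression contrasts equal differences of group medians.

#' Check loss
#'
#' @param u Residual vector.
#' @param tau Quantile level.
#' @return Total asymmetric absolute loss.
#' @export
check_loss <- function(u, tau) sum(u * (tau - (u < 0)))

#' Fit a linear quantile regression with bootstrap confidence intervals
#'
#' @param y Response vector (diagnostic interval in days).
#' @param X Design matrix or data frame of covariates. An intercept column is
#'   added unless one is already present (a constant column named
#'   `(Intercept)`).
#' @param tau Quantile level in (0, 1); 0.5 and 0.9 are the headline levels.
#' @param ci `"bootstrap"` (person-level resampling, percentile intervals) or
#'   `"none"`.
#' @param boot Number of bootstrap replicates.
#' @param seed Optional seed for the bootstrap resampling.
#' @param tie `"lower"` (default) resolves set-valued optima to the lower
#'   vertex, matching [quantile_lower()]; `"none"` fits at `tau` exactly and
#'   lets the simplex pick a vertex.
#' @param boot_method Solver for bootstrap replicates: `"fn"` (interior
#'   point, the default — much faster at large n and the vertex choice is
#'   immaterial inside a resampling distribution) or `"br"` (exact simplex).
#' @param stratum Optional stratum label stored on the result.
#' @param adjusted Optional flag stored on the result.
#' @return An object of class `dx_qr_fit`: a list with `coefficients`,
#'   `ci_lower`, `ci_upper`, `tau`, `n_obs`, `stratum`, `adjusted`,
#'   `objective` (check loss at the solution) and `boot` (the bootstrap
#'   coefficient draws, if computed).
#' @export
#' @examples
#' y <- c(3, 1, 4, 1, 5, 9, 2, 6)
#' f <- fit_quantile_regression(y, X = NULL, tau = 0.5, ci = "none")
#' f$coefficients # the lower-interpolation sample median
fit_quantile_regression <- function(y, X = NULL, tau = 0.5,
                                    ci = c("bootstrap", "none"), boot = 500L,
                                    seed = NULL, tie = c("lower", "none"),
                                    boot_method = c("fn", "br"),
                                    stratum = NA_character_,
                                    adjusted = NA) {
  ci <- match.arg(ci)
  tie <- match.arg(tie)
  boot_method <- match.arg(boot_method)
  if (ci == "bootstrap" && boot < 1) ci <- "none"
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) data_error("y contains missing values")
  X <- build_design(X, n)
  if (n <= ncol(X)) {
    data_error("Need more observations than design columns")
  }
  check_collinearity(X)
  if (tau <= 0 || tau >= 1) data_error("tau must be in (0, 1)")

  beta <- rq_solve(X, y, tau, tie)
  names(beta) <- colnames(X)

  ci_lower <- ci_upper <- rep(NA_real_, length(beta))
  boot_draws <- NULL
  degenerate <- stats::sd(y) == 0
  if (ci == "bootstrap") {
    if (degenerate) {
      warn("All responses identical: bootstrap intervals are zero-width")
      ci_lower <- ci_upper <- beta
    } else {
      if (!is.null(seed)) set.seed(as.integer(seed))
      boot_draws <- matrix(NA_real_, nrow = boot, ncol = length(beta))
      for (b in seq_len(boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        boot_draws[b, ] <- tryCatch(
          rq_solve(X[idx, , drop = FALSE], y[idx], tau, tie,
                   method = boot_method),
          error = function(e) rep(NA_real_, length(beta))
        )
      }
      qs <- apply(boot_draws, 2, quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE)
      # percentile intervals; widened (rarely needed) to contain the point
      # estimate so interval endpoints always bracket the coefficient
      ci_lower <- pmin(qs[1, ], beta)
      ci_upper <- pmax(qs[2, ], beta)
    }
    names(ci_lower) <- names(ci_upper) <- names(beta)
  }
  structure(
    list(coefficients = beta, ci_lower = ci_lower, ci_upper = ci_upper,
         tau = tau, n_obs = n, stratum = stratum, adjusted = adjusted,
         objective = check_loss(y - X %*% beta, tau), boot = boot_draws),
    class = "dx_qr_fit"
  )
}

#' @export
print.dx_qr_fit <- function(x, ...) {
  cat(sprintf("Quantile regression fit (tau = %g, n = %d%s)\n", x$tau, x$n_obs,
              if (!is.na(x$stratum)) paste0(", stratum = ", x$stratum) else ""))
  tab <- data.frame(estimate = x$coefficients, ci_lower = x$ci_lower,
                    ci_upper = x$ci_upper)
  print(round(tab, 3))
  invisible(x)
}

#' @export
coef.dx_qr_fit <- function(object, ...) object$coefficients

# Assemble the design matrix: NULL -> intercept only; add an intercept column
# when absent.
build_design <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  X <- as.matrix(X)
  if (ncol(X) == 0L) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != n) data_error("X and y have different lengths")
  has_intercept <- any(apply(X, 2, function(col) all(col == 1)))
  if (!has_intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  X
}

# Raise an error naming the dependent columns of a rank-deficient design.
check_collinearity <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    data_error(sprintf("Collinear design: column(s) %s are linearly dependent",
                       paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

# Check-loss solve at the (possibly tie-broken) quantile level; "br" is the
# exact simplex, "fn" the Frisch-Newton interior point.
rq_solve <- function(X, y, tau, tie = "lower", method = "br") {
  n <- length(y)
  tau_eff <- if (tie == "lower") tau - min(tau, 1 - tau) * 1e-3 / n else tau
  if (stats::sd(y) == 0) {
    # degenerate response: any solution fitting the constant is optimal
    beta <- rep(0, ncol(X))
    ic <- which(apply(X, 2, function(col) all(col == 1)))[1]
    beta[ic] <- y[1]
    return(beta)
  }
  fit <- if (method == "fn") {
    suppressWarnings(quantreg::rq.fit.fnb(X, y, tau = tau_eff))
  } else {
    suppressWarnings(quantreg::rq.fit.br(X, y, tau = tau_eff))
  }
  unname(fit$coefficients)
}
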