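#' Beta parameter pair for one marker class
#'
#' Lightweight container for the shape parameters of a Beta distribution
#' describing the methylation level of a marker region within one class
#' (e.g. tumor, normal, or a tissue type).
#'
#' @param alpha,beta Positive finite shape parameters.
#' @return An object of class `beta_params`: a named list with elements
#'   `alpha` and `beta`.
#' @examples
#' beta_params(2, 8)
#' @export
beta_params <- function(alpha, beta) {
  .check_shapes(alpha, beta)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(alpha = %g, beta = %g), mean = %.4f\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

.check_shapes <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      any(!is.finite(alpha)) || any(!is.finite(beta)) ||
      any(alpha <= 0) || any(beta <= 0)) {
    stop("beta shape parameters must be finite and > 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Marginal log-likelihood of a fragment's joint methylation state
#'
#' Model: a fragment drawn from a class has a latent methylation rate
#' p ~ Beta(alpha, beta) for the marker it overlaps; conditional on p, the
#' binary methylation states of its `n_cpg` CpG sites are i.i.d.
#' Bernoulli(p). Integrating p out gives the closed-form marginal of the
#' observed ordered state string with `k_meth` methylated sites:
#'
#' \deqn{P(k | n, \alpha, \beta) = B(\alpha + k, \beta + n - k) / B(\alpha, \beta)}
#'
#' computed via log-gamma. The binomial coefficient is deliberately
#' omitted: the datum is the specific ordered CpG state string, and the
#' coefficient cancels in every class ratio and mixture weight downstream.
#'
#' @param n_cpg Number of CpG sites on the fragment (non-negative integer).
#' @param k_meth Number of methylated sites, `0 <= k_meth <= n_cpg`.
#' @param alpha,beta Beta shape parameters of the class methylation-level
#'   distribution; `alpha` may also be a [beta_params()] object, in which
#'   case `beta` is ignored. All arguments recycle.
#' @return Numeric vector of log-likelihoods, each `<= 0`; a fragment with
#'   `n_cpg = 0` contributes 0 (empty product).
#' @examples
#' fragment_loglik(1, 1, 1, 1)        # log(1/2)
#' fragment_loglik(4, 4, beta_params(2, 8))
#' @export
fragment_loglik <- function(n_cpg, k_meth, alpha, beta = NULL) {
  if (inherits(alpha, "beta_params")) {
    beta <- alpha$beta
    alpha <- alpha$alpha
  }
  .check_shapes(alpha, beta)
  if (any(n_cpg < 0) || any(k_meth < 0) || any(k_meth > n_cpg)) {
    stop("need 0 <= k_meth <= n_cpg", call. = FALSE)
  }
  ll <- lbeta(alpha + k_meth, beta + n_cpg - k_meth) - lbeta(alpha, beta)
  # guard against tiny positive round-off at n_cpg = 0
  pmin(ll, 0)
}
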