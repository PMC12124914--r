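# Two-class fragment-likelihood mixture: maximum-likelihood tumor burden.

#' Estimate tumor burden from two-class fragment likelihoods
#'
#' Models the plasma cfDNA pool as a mixture of tumor-derived and
#' normal-derived fragments. With per-fragment marginal likelihoods
#' `L_t` and `L_n` (from [fragment_loglik()] under the tumor and normal
#' marker parameters), the tumor burden theta — the tumor-derived
#' fraction of cfDNA — maximizes
#' \deqn{\ell(\theta) = \sum_i \log[\theta L_{t,i} + (1-\theta) L_{n,i}]}
#' over \eqn{\theta \in [0, 1]}. The maximization is an exhaustive grid
#' search over `{0, grid_step, ..., 1}` (robust and auditable; the
#' objective is unimodal), with ties broken toward smaller theta. An
#' optional local refinement (`refine = TRUE`) polishes the grid optimum
#' with golden-section search in the bracketing interval.
#'
#' Optionally, the fragments with the most extreme absolute
#' log-likelihood ratio `|log L_t - log L_n|` — beyond the
#' `1 - trim_fraction` quantile — are excluded before optimization
#' (`trim_fraction > 0`), a robustness device against outlier fragments.
#' Trimming is off by default.
#'
#' @param loglik_tumor,loglik_normal Numeric vectors of per-fragment
#'   log-likelihoods under the tumor and normal class (same length,
#'   values `<= 0`, `-Inf` allowed for impossible fragments).
#' @param grid_step Grid resolution in `(0, 0.1]`; default 1e-4.
#' @param trim_fraction Fraction in `[0, 0.2]` of extreme-ratio
#'   fragments to exclude; default 0.
#' @param refine Logical; add golden-section refinement around the grid
#'   optimum.
#' @return Object of class `tumor_burden`: list with `theta`, `loglik`
#'   (objective at the optimum), `profile` (data.frame `theta`,
#'   `loglik` over the grid), `n_used`, `n_trimmed`.
#' @export
estimate_tumor_burden <- function(loglik_tumor, loglik_normal,
                                  grid_step = 1e-4, trim_fraction = 0,
                                  refine = FALSE) {
  lt <- as.numeric(loglik_tumor)
  ln <- as.numeric(loglik_normal)
  if (length(lt) != length(ln)) stop("likelihood vectors differ in length")
  if (length(lt) == 0) stop("no fragment evidence: empty likelihood vectors")
  if (!is.numeric(grid_step) || length(grid_step) != 1 ||
      grid_step <= 0 || grid_step > 0.1) {
    stop("grid_step must lie in (0, 0.1]")
  }
  if (trim_fraction < 0 || trim_fraction > 0.2) {
    stop("trim_fraction must lie in [0, 0.2]")
  }
  if (all(lt == -Inf & ln == -Inf)) {
    stop("all fragments have zero likelihood under both classes")
  }
  both_zero <- lt == -Inf & ln == -Inf
  if (any(both_zero)) {
    warning(sum(both_zero),
            " fragment(s) with zero likelihood under both classes dropped")
    lt <- lt[!both_zero]; ln <- ln[!both_zero]
  }
  n_trimmed <- 0L
  if (trim_fraction > 0) {
    d <- abs(lt - ln)
    q <- stats::quantile(d, 1 - trim_fraction, names = FALSE)
    keep <- d <= q
    n_trimmed <- sum(!keep)
    lt <- lt[keep]; ln <- ln[keep]
  }
  m <- pmax(lt, ln)
  a <- exp(lt - m)   # rescaled tumor likelihood, max(a, b) == 1
  b <- exp(ln - m)
  const <- sum(m)
  thetas <- seq(0, 1, by = grid_step)
  if (thetas[length(thetas)] < 1) thetas <- c(thetas, 1)
  obj <- function(theta) sum(log(theta * a + (1 - theta) * b)) + const
  # chunked matrix evaluation of the profile (vectorized over theta)
  prof <- numeric(length(thetas))
  chunk <- max(1L, floor(2e6 / max(1L, length(a))))
  for (s in seq(1, length(thetas), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(thetas))
    M <- a %o% thetas[idx] + b %o% (1 - thetas[idx])
    prof[idx] <- colSums(log(M)) + const
  }
  best <- which.max(prof)  # first maximum = smallest theta on ties
  theta_hat <- thetas[best]
  ll_hat <- prof[best]
  if (refine && length(thetas) > 2) {
    lo <- thetas[max(1L, best - 1L)]
    hi <- thetas[min(length(thetas), best + 1L)]
    op <- stats::optimize(obj, c(lo, hi), maximum = TRUE,
                          tol = .Machine$double.eps^0.5)
    if (op$objective > ll_hat + 1e-12) {
      theta_hat <- op$maximum
      ll_hat <- op$objective
    }
  }
  structure(list(theta = theta_hat, loglik = ll_hat,
                 profile = data.frame(theta = thetas, loglik = prof),
                 n_used = length(a), n_trimmed = n_trimmed),
            class = "tumor_burden")
}

#' @export
print.tumor_burden <- function(x, ...) {
  cat(sprintf("tumor burden theta = %.4f (log-lik %.3f, %d fragments used, %d trimmed)\n",
              x$theta, x$loglik, x$n_used, x$n_trimmed))
  invisible(x)
}

#' Tumor burden from a fragment table and a two-class marker set
#'
#' High-level wrapper: intersects fragments with the marker panel,
#' computes tumor/normal beta-Bernoulli likelihoods and maximizes the
#' two-class mixture ([estimate_tumor_burden()]).
#'
#' @param fragments Fragment table ([generate_frag_meth()] /
#'   [read_fragment_table()]).
#' @param markers A `marker_set` whose classes include `tumor_class` and
#'   `normal_class`.
#' @param tumor_class,normal_class Class names to use as the two mixture
#'   components.
#' @param ... Passed to [estimate_tumor_burden()].
#' @return A `tumor_burden` object.
#' @export
cancer_detector <- function(fragments, markers, tumor_class = "tumor",
                            normal_class = "normal", ...) {
  ev <- compute_fragment_evidence(fragments, markers)
  if (!all(c(tumor_class, normal_class) %in% ev$classes)) {
    stop("marker set lacks classes '", tumor_class, "' / '", normal_class, "'")
  }
  if (nrow(ev$info) == 0) {
    stop("no fragments overlap the marker regions; check coordinates and chromosomes")
  }
  estimate_tumor_burden(ev$loglik[, tumor_class], ev$loglik[, normal_class], ...)
}
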