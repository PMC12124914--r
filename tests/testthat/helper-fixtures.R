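# Shared fixture builders: tiny hand-written input files and an
# independent quadrature oracle for the beta-Bernoulli marginal.

write_bed <- function(rows, path = tempfile(fileext = ".bed")) {
  writeLines(vapply(rows, function(r) paste(r, collapse = "\t"), ""), path)
  path
}

write_calls <- function(rows, path = tempfile(fileext = ".txt"),
                        header = "Bismark methylation extractor") {
  writeLines(c(header,
               vapply(rows, function(r) paste(r, collapse = "\t"), "")),
             path)
  path
}

# Independent oracle: log of the integral  int p^k (1-p)^(n-k) dBeta(p; a, b)
# by adaptive quadrature under p = sin^2(t) (removes endpoint singularities
# for shapes >= 0.5), rescaled by the integrand peak so integrate() works at
# relative precision even when the marginal underflows.
quad_marginal_log <- function(n, k, a, b) {
  logf <- function(t) log(2) + (2 * k + 1) * log(sin(t)) +
    (2 * (n - k) + 1) * log(cos(t)) + stats::dbeta(sin(t)^2, a, b, log = TRUE)
  tg <- seq(1e-6, pi / 2 - 1e-6, length.out = 2001)
  c0 <- max(logf(tg))
  val <- stats::integrate(function(t) exp(logf(t) - c0), 0, pi / 2,
                          rel.tol = 1e-12, subdivisions = 400L)$value
  c0 + log(val)
}

# Direct (unvectorized, unscaled) evaluation of the mixture objective used
# as a brute-force cross-check for estimate_tumor_burden.
mixture_loglik_direct <- function(theta, lt, ln) {
  sum(log(theta * exp(lt) + (1 - theta) * exp(ln)))
}

# Canonical sortable view of a fragment table for round-trip comparison,
# with bookkeeping attributes (conflicts/rejects tallies) stripped.
frag_frame <- function(x) {
  cols <- c("chrom", "start", "end", "length", "n_cpg", "methState")
  x <- data.table::as.data.table(x)[, cols, with = FALSE]
  data.table::setorderv(x, cols)
  x <- as.data.frame(x)
  keep <- c("names", "class", "row.names")
  attributes(x)[setdiff(names(attributes(x)), keep)] <- NULL
  x
}
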