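# N-class fragment assignment with an unknown-tissue class, and the
# resulting cfDNA tissue-fraction estimate.

#' Assign a fragment to a class by the top-two fold-change rule
#'
#' A fragment is assigned to its maximum-likelihood class only when the
#' evidence is unambiguous: when the ratio of the two largest class
#' likelihoods (natural scale) is at least `fold_change`. Otherwise —
#' including an exact tie for first place — the fragment is classified as
#' ambiguous and labelled `"unknown"`.
#'
#' @param loglik Named numeric vector of per-class log-likelihoods
#'   (>= 2 classes).
#' @param fold_change Threshold `>= 1` on the top-two likelihood ratio;
#'   default 2.
#' @return A single class name, or `"unknown"`.
#' @examples
#' assign_fragment(c(liver = log(0.4), lung = log(0.3)))        # "unknown"
#' assign_fragment(c(liver = log(0.9), lung = log(0.3)))        # "liver"
#' @export
assign_fragment <- function(loglik, fold_change = 2) {
  if (length(loglik) < 2) stop("need likelihoods for at least 2 classes")
  if (is.null(names(loglik)) || any(!nzchar(names(loglik)))) {
    stop("loglik must be named by class")
  }
  if (!is.numeric(fold_change) || fold_change < 1) {
    stop("fold_change must be >= 1")
  }
  o <- order(loglik, decreasing = TRUE)
  l1 <- loglik[o[1]]; l2 <- loglik[o[2]]
  if (l1 == l2) return("unknown")                 # exact tie for first
  if (exp(l1 - l2) >= fold_change) names(loglik)[o[1]] else "unknown"
}

.assign_matrix <- function(L, fold_change) {
  # vectorized top-two rule over rows of a loglik matrix
  n <- nrow(L)
  if (n == 0) return(character())
  i1 <- max.col(L, ties.method = "first")
  top1 <- L[cbind(seq_len(n), i1)]
  L2 <- L
  L2[cbind(seq_len(n), i1)] <- -Inf
  i2 <- max.col(L2, ties.method = "first")
  top2 <- L2[cbind(seq_len(n), i2)]
  lab <- colnames(L)[i1]
  ambiguous <- (top1 == top2) | (exp(top1 - top2) < fold_change)
  lab[ambiguous] <- "unknown"
  lab
}

#' Deconvolve cfDNA tissue composition with an unknown class
#'
#' Assigns every fragment-marker evidence record to a tissue class by the
#' top-two fold-change rule ([assign_fragment()]) and reports per-class
#' fragment counts and fractions. Ambiguous fragments form the explicit
#' `unknown` component, so the reported fractions — including unknown —
#' always sum to 1; unknown mass is never redistributed.
#'
#' @param x A `fragment_evidence` object
#'   ([compute_fragment_evidence()]), a numeric log-likelihood matrix
#'   with class colnames, or a fragment table (in which case `markers`
#'   must be supplied).
#' @param markers Optional `marker_set`, used when `x` is a fragment
#'   table.
#' @param fold_change Top-two likelihood ratio threshold, `>= 1`;
#'   default 2.
#' @return Object of class `cf_deconvolution`: list with `class_counts`
#'   (named, known classes), `unknown_count`, `fractions` (named, known
#'   classes plus `"unknown"`, sums to 1), `n_fragments`, `fold_change`.
#' @export
cf_deconvolve <- function(x, markers = NULL, fold_change = 2) {
  if (!is.numeric(fold_change) || fold_change < 1) {
    stop("fold_change must be >= 1")
  }
  if (inherits(x, "fragment_evidence")) {
    L <- x$loglik
  } else if (is.matrix(x)) {
    L <- x
  } else {
    if (is.null(markers)) stop("supply a marker_set when x is a fragment table")
    L <- compute_fragment_evidence(x, markers)$loglik
  }
  if (ncol(L) < 2) stop("need at least 2 classes to deconvolve")
  if (is.null(colnames(L))) stop("log-likelihood matrix must have class colnames")
  if (nrow(L) == 0) {
    stop("no fragments overlap the marker regions; nothing to deconvolve ",
         "(check that fragment and marker coordinates share chromosomes)")
  }
  lab <- .assign_matrix(L, fold_change)
  classes <- colnames(L)
  counts <- stats::setNames(vapply(classes, function(cl) sum(lab == cl), 0L),
                            classes)
  unknown <- sum(lab == "unknown")
  total <- nrow(L)
  fractions <- c(counts, unknown = unknown) / total
  structure(list(class_counts = counts, unknown_count = unknown,
                 fractions = fractions, n_fragments = total,
                 fold_change = fold_change),
            class = "cf_deconvolution")
}

#' @export
print.cf_deconvolution <- function(x, ...) {
  cat(sprintf("cfDNA deconvolution over %d fragments (fold change >= %g):\n",
              x$n_fragments, x$fold_change))
  for (cl in names(x$fractions)) {
    cnt <- if (cl == "unknown") x$unknown_count else x$class_counts[[cl]]
    cat(sprintf("  %-12s %6d fragments  %.4f\n", cl, cnt, x$fractions[[cl]]))
  }
  invisible(x)
}

#' Pie chart of cfDNA tissue fractions
#'
#' Draws (and optionally writes) a pie chart of a cfDNA fraction vector,
#' one labelled wedge per class in descending fraction order.
#'
#' @param fractions Named non-negative numeric vector summing to 1
#'   (within `tol`), e.g. the `fractions` element of a
#'   `cf_deconvolution`, or the object itself.
#' @param file Optional output path; the device is chosen by extension
#'   (`.png`, `.svg`, `.pdf`). `NULL` draws on the current device.
#' @param tol Tolerance on `sum(fractions) == 1`.
#' @param main Plot title.
#' @return The output path (or `NULL`) invisibly.
#' @export
plot_fraction_pie <- function(fractions, file = NULL, tol = 1e-6,
                              main = "cfDNA tissue fractions") {
  if (inherits(fractions, "cf_deconvolution")) fractions <- fractions$fractions
  if (!is.numeric(fractions) || is.null(names(fractions))) {
    stop("fractions must be a named numeric vector")
  }
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > tol) {
    stop(sprintf("fractions must sum to 1 (got %.6f)", sum(fractions)))
  }
  fractions <- sort(fractions, decreasing = TRUE)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 1200, height = 900, res = 150),
           svg = grDevices::svg(file, width = 8, height = 6),
           pdf = grDevices::pdf(file, width = 8, height = 6),
           stop("unsupported image format: .", ext))
    on.exit(grDevices::dev.off())
  }
  keep <- fractions > 0
  labels <- sprintf("%s (%.1f%%)", names(fractions)[keep],
                    100 * fractions[keep])
  graphics::pie(fractions[keep], labels = labels, clockwise = TRUE,
                col = grDevices::hcl.colors(max(3, sum(keep)), "Temps"),
                main = main)
  invisible(file)
}
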