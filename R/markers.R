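# Marker regions: per-class Beta(alpha, beta) summaries of reference
# methylation levels, the "alpha:beta" marker file dialect, and
# fragment-marker intersection.

#' Fit a Beta distribution to reference methylation levels
#'
#' Summarizes the methylation levels (beta values in \[0, 1\]) of one
#' marker across a panel of reference samples of one class as a
#' Beta(alpha, beta) distribution. The default estimator is method of
#' moments: with sample mean `m` and sample variance `v` (n-1
#' denominator),
#' \deqn{\alpha = m\,(m(1-m)/v - 1), \quad \beta = (1-m)\,(m(1-m)/v - 1).}
#'
#' Degenerate panels are handled by a variance floor (`v` is raised to
#' `var_floor` when smaller, e.g. all values identical) and a clamp to
#' `0.99 * m * (1 - m)` when `v >= m(1-m)` (where the moment equations
#' would give non-positive shapes). Values of exactly 0 or 1 are
#' winsorized to `[winsorize, 1 - winsorize]` so downstream likelihoods
#' stay finite. By construction the fitted mean always equals the
#' (winsorized) sample mean.
#'
#' @param values Numeric methylation levels in \[0, 1\]; `NA`s dropped.
#'   At least 2 usable values are required.
#' @param var_floor Minimum variance used in the moment equations.
#' @param winsorize Boundary offset applied to values of exactly 0 or 1.
#' @param method `"moments"` (default, closed form) or `"mle"` (numeric
#'   maximum likelihood, moment fit as starting point).
#' @return A [beta_params()] object.
#' @examples
#' fit_beta_params(c(0.2, 0.4, 0.6))  # Beta(2, 3)
#' @export
fit_beta_params <- function(values, var_floor = 1e-6, winsorize = 1e-4,
                            method = c("moments", "mle")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 usable beta values")
  if (any(values < 0 | values > 1)) stop("beta values must lie in [0, 1]")
  values <- pmin(pmax(values, winsorize), 1 - winsorize)
  m <- mean(values)
  v <- stats::var(values)
  if (v < var_floor) {
    warning("sample variance below floor (", var_floor,
            "); using floored variance")
    v <- var_floor
  }
  if (v >= m * (1 - m)) v <- 0.99 * m * (1 - m)
  common <- m * (1 - m) / v - 1
  fit <- beta_params(m * common, (1 - m) * common)
  if (method == "mle") {
    nll <- function(par) -sum(stats::dbeta(values, exp(par[1]), exp(par[2]),
                                           log = TRUE))
    opt <- stats::optim(log(c(fit$alpha, fit$beta)), nll, method = "Nelder-Mead")
    fit <- beta_params(exp(opt$par[1]), exp(opt$par[2]))
  }
  fit
}

#' Construct a marker set
#'
#' A marker set bundles marker region coordinates with per-class Beta
#' shape parameters: the parametric reference describing how methylated
#' each marker is in each tissue/tumor class.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `marker_id` (unique).
#' @param alpha,beta Numeric matrices, markers x classes, with identical
#'   dimnames; column names are the class names. All entries positive
#'   and finite.
#' @return An object of class `marker_set`: list with elements `regions`
#'   (data.table), `classes`, `alpha`, `beta`.
#' @export
marker_set <- function(regions, alpha, beta) {
  regions <- data.table::as.data.table(regions)
  req <- c("chrom", "start", "end", "marker_id")
  if (!all(req %in% names(regions))) {
    stop("regions need columns: ", paste(req, collapse = ", "))
  }
  if (any(regions$start >= regions$end)) stop("marker regions need start < end")
  if (anyDuplicated(regions$marker_id)) stop("marker ids must be unique")
  alpha <- as.matrix(alpha); beta <- as.matrix(beta)
  if (!identical(dim(alpha), dim(beta))) stop("alpha/beta dimensions differ")
  if (nrow(alpha) != nrow(regions)) {
    stop("need one row of shape parameters per marker region")
  }
  if (is.null(colnames(alpha)) && !is.null(colnames(beta))) colnames(alpha) <- colnames(beta)
  if (is.null(colnames(alpha))) stop("alpha/beta must carry class names as colnames")
  if (is.null(colnames(beta))) colnames(beta) <- colnames(alpha)
  if (!identical(colnames(alpha), colnames(beta))) {
    beta <- beta[, colnames(alpha), drop = FALSE]
  }
  if (anyDuplicated(colnames(alpha))) stop("class names must be unique")
  .check_shapes(alpha, beta)
  rownames(alpha) <- rownames(beta) <- regions$marker_id
  structure(list(regions = regions[, req, with = FALSE],
                 classes = colnames(alpha), alpha = alpha, beta = beta),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d markers x %d classes (%s)\n",
              nrow(x$regions), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Fit marker parameters from a reference beta-value matrix
#'
#' For each marker and each class, fits a Beta distribution
#' ([fit_beta_params()]) to the methylation levels of the reference
#' samples belonging to that class.
#'
#' @param beta_matrix Numeric matrix markers x samples of methylation
#'   levels in \[0, 1\]; rownames are marker ids, colnames sample ids.
#' @param sample_classes data.frame with columns `sample_id`, `class`
#'   mapping every column of `beta_matrix` to a class.
#' @param regions Marker regions as for [marker_set()]; marker ids must
#'   match the rownames of `beta_matrix`.
#' @param ... Passed on to [fit_beta_params()].
#' @return A `marker_set`.
#' @export
fit_marker_params <- function(beta_matrix, sample_classes, regions, ...) {
  beta_matrix <- as.matrix(beta_matrix)
  sample_classes <- as.data.frame(sample_classes)
  if (!all(c("sample_id", "class") %in% names(sample_classes))) {
    stop("sample_classes needs columns sample_id, class")
  }
  miss <- setdiff(colnames(beta_matrix), sample_classes$sample_id)
  if (length(miss) > 0) {
    stop("samples without class assignment: ", paste(utils::head(miss, 3), collapse = ", "))
  }
  cls_of <- stats::setNames(as.character(sample_classes$class),
                            sample_classes$sample_id)[colnames(beta_matrix)]
  classes <- unique(unname(cls_of))
  A <- B <- matrix(NA_real_, nrow(beta_matrix), length(classes),
                   dimnames = list(rownames(beta_matrix), classes))
  for (cl in classes) {
    sub <- beta_matrix[, cls_of == cl, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      fit <- fit_beta_params(sub[i, ], ...)
      A[i, cl] <- fit$alpha
      B[i, cl] <- fit$beta
    }
  }
  regions <- data.table::as.data.table(regions)
  regions <- regions[match(rownames(beta_matrix), regions$marker_id)]
  if (anyNA(regions$marker_id)) stop("regions missing for some markers")
  marker_set(regions, A, B)
}

.fmt_shape <- function(x) sprintf("%#.6g", x)

#' Write / read the marker parameter file
#'
#' Tab-delimited marker dialect: a `#`-prefixed header naming the columns
#' `chrom, start, end, marker`, then one column per class; each data cell
#' holds the Beta shape pair formatted as `"alpha:beta"` with six
#' significant digits (e.g. `2.00000:3.00000`). Classes are matched by
#' header name on read, never by column position.
#'
#' @param markers A `marker_set`.
#' @param path Output (input) path, plain or `.gz`.
#' @return `write_marker_params()` returns `path` invisibly;
#'   `read_marker_params()` returns a `marker_set`.
#' @export
write_marker_params <- function(markers, path) {
  if (!inherits(markers, "marker_set")) stop("markers must be a marker_set")
  con <- .open_sink(path)
  on.exit(close(con))
  writeLines(paste0("#chrom\tstart\tend\tmarker\t",
                    paste(markers$classes, collapse = "\t")), con)
  tok <- matrix(paste0(.fmt_shape(markers$alpha), ":", .fmt_shape(markers$beta)),
                nrow = nrow(markers$alpha))
  body <- cbind(markers$regions$chrom, markers$regions$start,
                markers$regions$end, markers$regions$marker_id, tok)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_params
#' @export
read_marker_params <- function(path) {
  con <- .open_src(path)
  lines <- readLines(con)
  close(con)
  if (length(lines) < 2 || !startsWith(lines[1], "#")) {
    stop("marker file needs a '#' header line and at least one marker row")
  }
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(header) < 5) stop("marker file header needs >= 2 class columns")
  classes <- header[-(1:4)]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  nc <- lengths(rows)
  if (any(nc != length(header))) {
    stop("marker file line ", which(nc != length(header))[1] + 1,
         ": wrong number of columns")
  }
  m <- length(rows)
  regions <- data.table::data.table(
    chrom = vapply(rows, `[`, "", 1),
    start = as.integer(vapply(rows, `[`, "", 2)),
    end = as.integer(vapply(rows, `[`, "", 3)),
    marker_id = vapply(rows, `[`, "", 4)
  )
  A <- B <- matrix(NA_real_, m, length(classes),
                   dimnames = list(regions$marker_id, classes))
  for (i in seq_len(m)) {
    for (j in seq_along(classes)) {
      tok <- rows[[i]][4 + j]
      parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
      shapes <- suppressWarnings(as.numeric(parts))
      if (length(shapes) != 2 || anyNA(shapes)) {
        stop("marker file line ", i + 1, ", column ", 4 + j,
             ": malformed shape token '", tok, "'")
      }
      if (any(!is.finite(shapes)) || any(shapes <= 0)) {
        stop("marker file line ", i + 1, ", column ", 4 + j,
             ": shape parameters must be finite and > 0 (got '", tok, "')")
      }
      A[i, j] <- shapes[1]
      B[i, j] <- shapes[2]
    }
  }
  marker_set(regions, A, B)
}

#' Intersect fragments with marker regions
#'
#' Emits one row per (fragment, marker) pair overlapping by at least one
#' base (0-based half-open intervals on both sides). Fragments that
#' overlap no marker are dropped; a fragment spanning several markers is
#' emitted once per marker.
#'
#' @param fragments Fragment table (needs `fragment_id`, `chrom`,
#'   `start`, `end`).
#' @param markers A `marker_set`.
#' @return `data.table` with columns `fragment_id`, `marker_id` plus the
#'   fragment row index `frag_row`. May have zero rows.
#' @export
intersect_markers <- function(fragments, markers) {
  fragments <- data.table::as.data.table(fragments)
  if (!inherits(markers, "marker_set")) stop("markers must be a marker_set")
  if (nrow(fragments) == 0) {
    return(data.table::data.table(frag_row = integer(),
                                  fragment_id = character(),
                                  marker_id = character()))
  }
  # 0-based half-open -> 1-based closed for IRanges
  fr <- GenomicRanges::GRanges(fragments$chrom,
                               IRanges::IRanges(fragments$start + 1L,
                                                fragments$end))
  mr <- GenomicRanges::GRanges(markers$regions$chrom,
                               IRanges::IRanges(markers$regions$start + 1L,
                                                markers$regions$end))
  hits <- GenomicRanges::findOverlaps(fr, mr, minoverlap = 1L)
  data.table::data.table(
    frag_row = S4Vectors::queryHits(hits),
    fragment_id = fragments$fragment_id[S4Vectors::queryHits(hits)],
    marker_id = markers$regions$marker_id[S4Vectors::subjectHits(hits)]
  )
}

#' Compute per-class fragment log-likelihoods over a marker panel
#'
#' Intersects fragments with markers and evaluates, for every retained
#' (fragment, marker) pair and every class, the beta-Bernoulli marginal
#' log-likelihood ([fragment_loglik()]) of the fragment's methylation
#' state under that class's shape parameters for that marker. Fragments
#' overlapping several markers contribute one evidence row per marker
#' (markers are treated as independent evidence sources).
#'
#' @param fragments Fragment table with `fragment_id`, `chrom`, `start`,
#'   `end`, `n_cpg`, `methState`.
#' @param markers A `marker_set`.
#' @return Object of class `fragment_evidence`: list with `info` (a
#'   data.table `fragment_id`, `marker_id`, `n_cpg`, `k_meth`), `loglik`
#'   (matrix, evidence rows x classes) and `classes`.
#' @export
compute_fragment_evidence <- function(fragments, markers) {
  fragments <- data.table::as.data.table(fragments)
  hits <- intersect_markers(fragments, markers)
  n <- fragments$n_cpg[hits$frag_row]
  k <- count_meth(fragments$methState[hits$frag_row])
  mrow <- match(hits$marker_id, markers$regions$marker_id)
  L <- matrix(NA_real_, nrow(hits), length(markers$classes),
              dimnames = list(NULL, markers$classes))
  for (j in seq_along(markers$classes)) {
    L[, j] <- fragment_loglik(n, k, markers$alpha[mrow, j],
                              markers$beta[mrow, j])
  }
  structure(list(
    info = data.table::data.table(fragment_id = hits$fragment_id,
                                  marker_id = hits$marker_id,
                                  n_cpg = n, k_meth = k),
    loglik = L,
    classes = markers$classes
  ), class = "fragment_evidence")
}

#' @export
print.fragment_evidence <- function(x, ...) {
  cat(sprintf("fragment_evidence: %d fragment-marker records, classes: %s\n",
              nrow(x$info), paste(x$classes, collapse = ", ")))
  invisible(x)
}
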