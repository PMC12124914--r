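# Ground-truthed synthetic cfDNA world: marker panels on a toy
# chromosome, fragment populations drawn from known tissue mixtures, and
# emission of the Bismark-style file dialects the ingestion layer reads.

#' Build a simulation configuration
#'
#' Describes a synthetic cfDNA world: a panel of non-overlapping
#' fixed-width marker regions on a toy chromosome, per-class Beta
#' methylation-level parameters for every marker, a true tissue mixture,
#' and fragment geometry (length and CpG-count distributions echoing
#' typical plasma cfDNA: modal length ~167 bp).
#'
#' If `alpha`/`beta` are not supplied, each marker receives class means
#' drawn as a random permutation of `class_means` (so every class is
#' hyper-, mid- or hypo-methylated on a rotating share of markers),
#' converted to shapes by `alpha = mu * concentration`,
#' `beta = (1 - mu) * concentration`.
#'
#' @param mixture Named numeric vector of true class fractions, summing
#'   to 1; names are the class names.
#' @param n_fragments Number of fragments to simulate.
#' @param n_markers Number of marker regions.
#' @param alpha,beta Optional markers x classes shape matrices (colnames
#'   = class names). Vectors of length `n_classes` are recycled across
#'   markers.
#' @param class_means Per-class mean methylation levels permuted across
#'   markers when `alpha`/`beta` are not given.
#' @param concentration Beta concentration (alpha + beta) used with
#'   `class_means`.
#' @param cpg_min,cpg_max CpG count per fragment ~ uniform on
#'   `{cpg_min, ..., cpg_max}`.
#' @param fraglen_mean,fraglen_sd,fraglen_min,fraglen_max Fragment
#'   length ~ round(Normal(mean, sd)) truncated to `[min, max]`.
#' @param marker_width,marker_gap Marker geometry on the toy chromosome.
#' @param chrom Toy chromosome name.
#' @param seed RNG seed: a fixed seed makes [simulate_fragments()] and
#'   [emit_bismark_dialect()] byte-reproducible.
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(mixture, n_fragments = 5000, n_markers = 30,
                              alpha = NULL, beta = NULL,
                              class_means = NULL, concentration = 50,
                              cpg_min = 3, cpg_max = 8,
                              fraglen_mean = 167, fraglen_sd = 20,
                              fraglen_min = 80, fraglen_max = 400,
                              marker_width = 1000, marker_gap = 1000,
                              chrom = "chrS", seed = 1L) {
  if (is.null(names(mixture)) || any(!nzchar(names(mixture)))) {
    stop("mixture must be named by class")
  }
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-9) {
    stop("mixture fractions must be non-negative and sum to 1")
  }
  classes <- names(mixture)
  if (length(classes) < 2) stop("need at least 2 classes")
  if (n_fragments < 1 || n_markers < 1) stop("counts must be positive")
  if (cpg_min < 0 || cpg_max < cpg_min) stop("invalid CpG count range")
  if (fraglen_min < 10 || fraglen_max < fraglen_min) stop("invalid length range")
  if (cpg_max > floor((fraglen_min - 4) / 2)) {
    stop("cpg_max too large for fraglen_min (CpGs are placed 2 bp apart)")
  }
  if (fraglen_max > marker_width) stop("fraglen_max must fit inside a marker")
  if (!is.null(alpha)) {
    if (is.null(dim(alpha))) alpha <- matrix(alpha, n_markers, length(classes),
                                             byrow = TRUE)
    if (is.null(dim(beta))) beta <- matrix(beta, n_markers, length(classes),
                                           byrow = TRUE)
    colnames(alpha) <- colnames(beta) <- classes
    .check_shapes(alpha, beta)
  } else {
    if (is.null(class_means)) {
      # spread class means over (0, 1): well-separated by construction
      class_means <- seq(0.02, 0.98, length.out = length(classes))
    }
    if (length(class_means) != length(classes)) {
      stop("class_means must have one entry per class")
    }
  }
  structure(list(
    classes = classes, mixture = mixture, n_fragments = as.integer(n_fragments),
    n_markers = as.integer(n_markers), alpha = alpha, beta = beta,
    class_means = class_means, concentration = concentration,
    cpg_min = as.integer(cpg_min), cpg_max = as.integer(cpg_max),
    fraglen_mean = fraglen_mean, fraglen_sd = fraglen_sd,
    fraglen_min = as.integer(fraglen_min), fraglen_max = as.integer(fraglen_max),
    marker_width = as.integer(marker_width), marker_gap = as.integer(marker_gap),
    chrom = chrom, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Canonical two-class (tumor vs normal) world
#'
#' Tumor markers hyper-methylated in tumor, hypo in normal:
#' Beta(8, 2) vs Beta(2, 8) on every marker, CpG counts uniform on
#' 3..8. `theta` is the true tumor burden.
#'
#' @param theta True tumor-derived cfDNA fraction in `[0, 1]`.
#' @param n_fragments,seed,... Passed to [simulation_config()].
#' @return A `simulation_config` with classes `tumor`, `normal`.
#' @export
two_class_config <- function(theta, n_fragments = 5000, seed = 1L, ...) {
  simulation_config(
    mixture = c(tumor = theta, normal = 1 - theta),
    n_fragments = n_fragments,
    alpha = c(8, 2), beta = c(2, 8),
    cpg_min = 3, cpg_max = 8,
    seed = seed, ...
  )
}

#' Canonical well-separated multi-tissue world
#'
#' Three-tissue mixture over a CpG-dense marker panel: per marker the
#' class means are a random permutation of `{0.02, 0.5, 0.98}` at
#' concentration 50, CpG counts uniform on 8..16. Tissue markers in
#' real panels are selected for exactly this property — strong
#' between-class contrast and high CpG density — so this is the world in
#' which per-fragment assignment is nearly always unambiguous.
#'
#' @param mixture Named true tissue fractions (default liver 0.1,
#'   lung 0.2, blood 0.7).
#' @param n_fragments,seed,... Passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
multi_tissue_config <- function(mixture = c(liver = 0.1, lung = 0.2,
                                            blood = 0.7),
                                n_fragments = 10000, seed = 1L, ...) {
  means <- if (length(mixture) == 3) c(0.02, 0.5, 0.98) else NULL
  simulation_config(
    mixture = mixture, n_fragments = n_fragments,
    class_means = means,
    concentration = 50, cpg_min = 8, cpg_max = 16,
    seed = seed, ...
  )
}

#' Marker regions and truth parameters implied by a configuration
#'
#' Materializes the marker panel of a `simulation_config` as a
#' [marker_set()]: non-overlapping fixed-width intervals on the toy
#' chromosome with the per-class Beta shape parameters the generator
#' draws from. Deterministic given the config seed.
#'
#' @param config A `simulation_config`.
#' @return A `marker_set`.
#' @export
config_marker_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$n_markers
  starts <- (seq_len(m) - 1L) * (config$marker_width + config$marker_gap)
  regions <- data.table::data.table(
    chrom = config$chrom, start = starts, end = starts + config$marker_width,
    marker_id = sprintf("M%04d", seq_len(m))
  )
  if (!is.null(config$alpha)) {
    A <- config$alpha; B <- config$beta
    if (nrow(A) != m) {
      A <- A[rep_len(seq_len(nrow(A)), m), , drop = FALSE]
      B <- B[rep_len(seq_len(nrow(B)), m), , drop = FALSE]
    }
  } else {
    k <- length(config$classes)
    # per-marker permutation of class means, deterministic in the seed
    set.seed(config$seed + 104729L)
    mus <- t(vapply(seq_len(m), function(i) sample(config$class_means),
                    numeric(k)))
    A <- mus * config$concentration
    B <- (1 - mus) * config$concentration
    colnames(A) <- colnames(B) <- config$classes
  }
  marker_set(regions, A, B)
}

#' Simulate a ground-truthed cfDNA fragment population
#'
#' Generative model, per fragment: tissue class ~ `mixture`; marker ~
#' uniform over the panel; latent methylation rate
#' p ~ Beta(alpha\[marker, class\], beta\[marker, class\]); CpG count ~
#' uniform on the configured range; each CpG state ~ Bernoulli(p)
#' independently (so the methylated count is Binomial(n_cpg, p),
#' realized as an ordered state string). Fragment intervals are placed
#' uniformly inside their marker; CpG sites sit 2 bp apart at odd
#' offsets from the fragment start.
#'
#' @param config A `simulation_config`.
#' @param seed Optional override of `config$seed`.
#' @return Object of class `cfdna_simulation`: list with `fragments` (a
#'   data.table: `fragment_id`, `chrom`, `start`, `end`, `length`,
#'   `strand`, `marker_id`, `class` (truth), `n_cpg`, `k_meth`,
#'   `methState`, `cpg_pos` (comma-joined 0-based positions)), `markers`
#'   (the [config_marker_set()]), and `config`.
#' @export
simulate_fragments <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  markers <- config_marker_set(config)   # panel fixed by the config seed
  sim_seed <- if (is.null(seed)) config$seed else as.integer(seed)
  set.seed(sim_seed)
  n <- config$n_fragments
  cls <- sample(config$classes, n, replace = TRUE, prob = config$mixture)
  mrow <- sample.int(config$n_markers, n, replace = TRUE)
  jcol <- match(cls, markers$classes)
  p <- stats::rbeta(n, markers$alpha[cbind(mrow, jcol)],
                    markers$beta[cbind(mrow, jcol)])
  len <- pmin(pmax(round(stats::rnorm(n, config$fraglen_mean,
                                      config$fraglen_sd)),
                   config$fraglen_min), config$fraglen_max)
  n_cpg <- config$cpg_min +
    sample.int(config$cpg_max - config$cpg_min + 1L, n, replace = TRUE) - 1L
  ms <- markers$regions$start[mrow]
  offset <- floor(stats::runif(n) * (config$marker_width - len + 1))
  start <- ms + as.integer(offset)
  end <- start + as.integer(len)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  # candidate CpG sites: odd offsets, C and G both inside the fragment
  cpg_pos <- character(n)
  meth <- character(n)
  k_meth <- integer(n)
  for (i in seq_len(n)) {
    if (n_cpg[i] == 0L) {
      cpg_pos[i] <- ""
      meth[i] <- ""
      next
    }
    cand <- seq(start[i] + 1L, end[i] - 3L, by = 2L)
    pos <- sort(sample(cand, n_cpg[i]))
    st <- stats::rbinom(n_cpg[i], 1L, p[i])
    cpg_pos[i] <- paste(pos, collapse = ",")
    meth[i] <- paste(st, collapse = "")
    k_meth[i] <- sum(st)
  }
  frags <- data.table::data.table(
    fragment_id = sprintf("S%06d", seq_len(n)),
    chrom = config$chrom, start = start, end = end,
    length = as.integer(len), strand = strand,
    marker_id = markers$regions$marker_id[mrow],
    class = cls, n_cpg = as.integer(n_cpg), k_meth = k_meth,
    methState = meth, cpg_pos = cpg_pos
  )
  structure(list(fragments = frags, markers = markers, config = config),
            class = "cfdna_simulation")
}

#' @export
print.cfdna_simulation <- function(x, ...) {
  cat(sprintf("cfdna_simulation: %d fragments, %d markers, classes: %s (seed %d)\n",
              nrow(x$fragments), nrow(x$markers$regions),
              paste(x$config$classes, collapse = ", "), x$config$seed))
  invisible(x)
}

#' Emit a simulation in the Bismark-style input dialects
#'
#' Writes the files the ingestion layer consumes — a paired-end read BED,
#' CpG_OT / CpG_OB methylation call files — plus a ground-truth sidecar.
#' Each fragment is split into two mates covering the first and last two
#' thirds of the interval, so the middle third is reported by both mates
#' and the duplicate-agreement merge path is exercised on every fragment.
#' Calls from `+` fragments go to the OT file (1-based C position);
#' calls from `-` fragments go to the OB file (1-based G position).
#'
#' With `conflict_rate > 0`, a fragment (with that probability) gains a
#' decoy CpG in the mate-overlap region, reported methylated by one mate
#' and unmethylated by the other. Decoys sit at even offsets, where the
#' generator never places a true CpG, so the ingestion conflict rule
#' drops exactly the decoys and the reconstructed fragments still equal
#' the simulated truth.
#'
#' @param sim A `cfdna_simulation`.
#' @param dir Output directory (created if needed).
#' @param conflict_rate Per-fragment decoy-conflict probability in
#'   `[0, 1]`.
#' @param seed RNG seed for conflict placement; default derived from the
#'   simulation seed.
#' @return Named list of file paths (`reads`, `calls_ot`, `calls_ob`,
#'   `truth`) with attribute `n_conflicts_injected`.
#' @export
emit_bismark_dialect <- function(sim, dir, conflict_rate = 0, seed = NULL) {
  stopifnot(inherits(sim, "cfdna_simulation"))
  if (conflict_rate < 0 || conflict_rate > 1) stop("conflict_rate in [0, 1]")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(if (is.null(seed)) sim$config$seed + 7919L else as.integer(seed))
  fr <- sim$fragments
  n <- nrow(fr)
  half <- as.integer(ceiling(2 * fr$length / 3))
  m1s <- fr$start; m1e <- fr$start + half
  m2s <- fr$end - half; m2e <- fr$end
  reads <- data.table::data.table(
    chrom = rep(fr$chrom, 2L),
    start = c(m1s, m2s), end = c(m1e, m2e),
    name = c(paste0(fr$fragment_id, "/1"), paste0(fr$fragment_id, "/2")),
    score = 0L, strand = rep(fr$strand, 2L),
    ord = c(seq_len(n), seq_len(n) + 0.5)
  )
  data.table::setorder(reads, ord)
  reads[, ord := NULL]

  pos_list <- strsplit(fr$cpg_pos, ",", fixed = TRUE)
  st_list <- strsplit(fr$methState, "", fixed = TRUE)
  per_frag <- lengths(pos_list)
  per_frag[fr$n_cpg == 0L] <- 0L
  idx <- rep(seq_len(n), per_frag)
  pos <- as.integer(unlist(pos_list[per_frag > 0]))
  st <- as.integer(unlist(st_list[per_frag > 0]))
  calls <- data.table::data.table(
    frag = idx, pos0 = pos, state = st,
    read_id = fr$fragment_id[idx], chrom = fr$chrom[idx],
    strand = fr$strand[idx]
  )
  in1 <- calls$pos0 >= m1s[calls$frag] & calls$pos0 + 1L < m1e[calls$frag]
  in2 <- calls$pos0 >= m2s[calls$frag] & calls$pos0 + 1L < m2e[calls$frag]
  mate_calls <- data.table::rbindlist(list(
    calls[in1][, mate := 1L],
    calls[in2][, mate := 2L]
  ))

  injected <- 0L
  if (conflict_rate > 0) {
    hit <- which(stats::runif(n) < conflict_rate)
    decoys <- list()
    for (i in hit) {
      lo <- m2s[i] + (m2s[i] - fr$start[i]) %% 2L        # even offset
      cand <- seq(lo, m1e[i] - 2L, by = 2L)
      cand <- cand[cand >= m2s[i]]
      if (length(cand) == 0) next
      dpos <- cand[sample.int(length(cand), 1L)]
      decoys[[length(decoys) + 1L]] <- data.table::data.table(
        frag = i, pos0 = dpos, state = c(1L, 0L),
        read_id = fr$fragment_id[i], chrom = fr$chrom[i],
        strand = fr$strand[i], mate = c(1L, 2L)
      )
      injected <- injected + 1L
    }
    if (length(decoys) > 0) {
      mate_calls <- data.table::rbindlist(list(mate_calls,
                                               data.table::rbindlist(decoys)))
    }
  }
  data.table::setorder(mate_calls, frag, mate, pos0, -state)

  fmt_calls <- function(dt, ot) {
    if (nrow(dt) == 0) return(character())
    pos1 <- dt$pos0 + if (ot) 1L else 2L
    paste(paste0(dt$read_id, "/", dt$mate),
          ifelse(dt$state == 1L, "+", "-"),
          dt$chrom, pos1, ifelse(dt$state == 1L, "Z", "z"),
          sep = "\t")
  }
  paths <- list(reads = file.path(dir, "reads.bed"),
                calls_ot = file.path(dir, "CpG_OT_sim.txt"),
                calls_ob = file.path(dir, "CpG_OB_sim.txt"),
                truth = file.path(dir, "truth.tsv"))
  utils::write.table(reads, paths$reads, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(c("Bismark methylation extractor (synthetic dialect)",
               fmt_calls(mate_calls[strand == "+"], ot = TRUE)),
             paths$calls_ot)
  writeLines(c("Bismark methylation extractor (synthetic dialect)",
               fmt_calls(mate_calls[strand == "-"], ot = FALSE)),
             paths$calls_ob)
  truth <- fr[, .(fragment_id, class)]
  con <- file(paths$truth, "wt")
  writeLines("#fragment_id\tclass", con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  attr(paths, "n_conflicts_injected") <- injected
  paths
}
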