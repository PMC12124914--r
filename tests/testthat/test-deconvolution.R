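# Core inference: beta-Bernoulli likelihood, tumor-burden mixture MLE,
# fold-change assignment, tissue fractions.

test_that("fragment_loglik matches closed forms and the quadrature oracle", {
  expect_identical(fragment_loglik(0, 0, 5, 5), 0)          # empty product
  expect_equal(fragment_loglik(1, 1, 1, 1), log(1 / 2))     # uniform prior
  # fully methylated 4-CpG fragment under a hypomethylated class:
  # B(6,8)/B(2,8) = 1/143 exactly
  expect_equal(fragment_loglik(4, 4, 2, 8), log(1 / 143), tolerance = 1e-12)
  expect_equal(fragment_loglik(4, 4, 2, 8), quad_marginal_log(4, 4, 2, 8),
               tolerance = 1e-9)
  expect_equal(fragment_loglik(7, 3, beta_params(0.5, 8)),
               quad_marginal_log(7, 3, 0.5, 8), tolerance = 1e-9)
  expect_true(all(fragment_loglik(0:10, 0, 2, 2) <= 0))

  expect_error(fragment_loglik(3, 4, 1, 1), "k_meth")
  expect_error(fragment_loglik(3, 1, -1, 1), "> 0")
  expect_error(fragment_loglik(3, 1, 1, Inf), "> 0")
})

test_that("tumor burden: tie-break, boundary forcing and brute-force agreement", {
  # flat likelihood: every theta equivalent -> smallest wins
  flat <- estimate_tumor_burden(rep(log(0.3), 50), rep(log(0.3), 50),
                                grid_step = 0.01)
  expect_equal(flat$theta, 0)
  expect_equal(nrow(flat$profile), 101L)

  # normal likelihood zero everywhere -> theta forced to 1
  forced <- estimate_tumor_burden(rep(log(0.5), 20), rep(-Inf, 20),
                                  grid_step = 0.01)
  expect_equal(forced$theta, 1)

  # grid argmax equals independent direct evaluation of the objective
  set.seed(19)
  lt <- log(runif(200)); ln <- log(runif(200))
  fit <- estimate_tumor_burden(lt, ln, grid_step = 0.001)
  grid <- seq(0, 1, by = 0.001)
  direct <- vapply(grid, mixture_loglik_direct, 0, lt = lt, ln = ln)
  expect_equal(fit$theta, grid[which.max(direct)])
  expect_equal(fit$loglik, max(direct), tolerance = 1e-9)
  expect_equal(fit$profile$loglik, direct, tolerance = 1e-9)
})

test_that("tumor burden input contracts are enforced", {
  expect_error(estimate_tumor_burden(numeric(), numeric()), "empty")
  expect_error(estimate_tumor_burden(log(0.1), c(log(0.1), log(0.2))), "length")
  expect_error(estimate_tumor_burden(-Inf, -Inf), "zero likelihood")
  expect_error(estimate_tumor_burden(log(0.5), log(0.5), grid_step = 0.5),
               "grid_step")
  expect_error(estimate_tumor_burden(log(0.5), log(0.5), trim_fraction = 0.5),
               "trim_fraction")
})

test_that("appending a tumor-favoring fragment never decreases theta-hat", {
  set.seed(23)
  for (rep in 1:5) {
    lt <- log(runif(100)); ln <- log(runif(100))
    base <- estimate_tumor_burden(lt, ln, grid_step = 0.005)$theta
    extra_t <- estimate_tumor_burden(c(lt, log(0.9)), c(ln, log(0.05)),
                                     grid_step = 0.005)$theta
    expect_gte(extra_t, base)
  }
})

test_that("trimming removes the extreme likelihood-ratio tail", {
  set.seed(29)
  lt <- log(runif(200)); ln <- log(runif(200))
  lt[1:4] <- 0; ln[1:4] <- -40          # extreme tumor-like outliers
  trimmed <- estimate_tumor_burden(lt, ln, grid_step = 0.001,
                                   trim_fraction = 0.02)
  expect_equal(trimmed$n_trimmed, 4L)
  expect_equal(trimmed$n_used, 196L)
  plain <- estimate_tumor_burden(lt, ln, grid_step = 0.001)
  expect_lt(trimmed$theta, plain$theta)  # outliers no longer inflate theta
})

test_that("golden-section refinement only improves the objective", {
  set.seed(37)
  lt <- log(runif(500)); ln <- log(runif(500))
  coarse <- estimate_tumor_burden(lt, ln, grid_step = 0.01)
  fine <- estimate_tumor_burden(lt, ln, grid_step = 0.01, refine = TRUE)
  expect_gte(fine$loglik, coarse$loglik)
  expect_lt(abs(fine$theta - coarse$theta), 0.01)
})

test_that("theta recovery on the simulated two-class world", {
  sim <- simulate_fragments(two_class_config(0.2, n_fragments = 2000,
                                             seed = 71))
  tb <- cancer_detector(sim$fragments, sim$markers, grid_step = 0.001)
  expect_lt(abs(tb$theta - 0.2), 0.03)
  expect_equal(tb$n_used, 2000L)
})

test_that("assign_fragment applies the top-two fold-change rule", {
  expect_equal(assign_fragment(log(c(a = 0.4, b = 0.3))), "unknown")  # 1.33 < 2
  expect_equal(assign_fragment(log(c(a = 0.9, b = 0.3, c = 0.1))), "a")
  expect_equal(assign_fragment(log(c(a = 0.5, b = 0.5))), "unknown")  # tie
  expect_equal(assign_fragment(log(c(a = 0.5, b = 0.5)), fold_change = 1),
               "unknown")                                             # tie wins
  expect_equal(assign_fragment(log(c(a = 0.4, b = 0.3)), fold_change = 1.2),
               "a")
  expect_error(assign_fragment(c(a = -1)), "2 classes")
  expect_error(assign_fragment(log(c(a = 0.4, b = 0.3)), fold_change = 0.5),
               ">= 1")
})

test_that("cf_deconvolve normalizes counts and keeps the unknown component", {
  # craft a likelihood matrix giving counts liver 60, lung 30, unknown 10
  L <- rbind(
    matrix(rep(log(c(0.9, 0.1, 0.05)), 60), ncol = 3, byrow = TRUE),
    matrix(rep(log(c(0.1, 0.9, 0.05)), 30), ncol = 3, byrow = TRUE),
    matrix(rep(log(c(0.4, 0.3, 0.05)), 10), ncol = 3, byrow = TRUE)
  )
  colnames(L) <- c("liver", "lung", "blood")
  dec <- cf_deconvolve(L, fold_change = 2)
  expect_equal(unname(dec$class_counts), c(60L, 30L, 0L))
  expect_equal(dec$unknown_count, 10L)
  expect_equal(unname(dec$fractions),
               c(0.6, 0.3, 0, 0.1))
  expect_equal(sum(dec$fractions), 1, tolerance = 1e-12)

  # all ambiguous -> unknown fraction 1
  Lx <- matrix(log(0.2), 25, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(cf_deconvolve(Lx)$fractions[["unknown"]], 1)

  expect_error(cf_deconvolve(L[, 1, drop = FALSE]), "2 classes")
  expect_error(cf_deconvolve(L[0, ]), "no fragments")
})

test_that("two-class deconvolution agrees with direct per-fragment comparison", {
  sim <- simulate_fragments(two_class_config(0.3, n_fragments = 800,
                                             seed = 83))
  ev <- compute_fragment_evidence(sim$fragments, sim$markers)
  dec <- cf_deconvolve(ev, fold_change = 2)
  # oracle: independent row-wise likelihood comparison
  lab <- apply(ev$loglik, 1, function(l) {
    r <- exp(max(l) - max(l[-which.max(l)]))
    if (l[1] == l[2]) "unknown"
    else if (r >= 2) names(l)[which.max(l)] else "unknown"
  })
  expect_equal(unname(dec$class_counts["tumor"]),
               unname(sum(lab == "tumor")))
  expect_equal(dec$unknown_count, sum(lab == "unknown"))
  # strongly tumor-like fragments land in the tumor class
  strong <- ev$info$k_meth == ev$info$n_cpg & ev$info$n_cpg >= 4
  expect_true(all(lab[strong] == "tumor"))
})

test_that("fractions sum to 1 and permuting classes permutes, not changes, them", {
  set.seed(53)
  L <- matrix(log(runif(300)), 100, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  dec <- cf_deconvolve(L)
  expect_equal(sum(dec$fractions), 1, tolerance = 1e-12)
  perm <- c("c", "a", "b")
  dec2 <- cf_deconvolve(L[, perm])
  expect_equal(dec2$fractions[c("a", "b", "c")],
               dec$fractions[c("a", "b", "c")])
  expect_equal(dec2$fractions[["unknown"]], dec$fractions[["unknown"]])
})

test_that("raising the fold-change threshold never shrinks the unknown fraction", {
  set.seed(59)
  L <- matrix(log(runif(600)), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  unk <- vapply(c(1, 2, 5, 10),
                function(fc) cf_deconvolve(L, fold_change = fc)$fractions[["unknown"]],
                0)
  expect_true(all(diff(unk) >= 0))
})

test_that("plot_fraction_pie writes an image and enforces its contract", {
  p <- tempfile(fileext = ".png")
  plot_fraction_pie(c(A = 1), p)
  expect_true(file.exists(p) && file.size(p) > 0)

  p2 <- tempfile(fileext = ".svg")
  plot_fraction_pie(c(A = 0.5, B = 0.5), p2)
  expect_true(file.exists(p2) && file.size(p2) > 0)

  expect_error(plot_fraction_pie(c(A = 0.5, B = 0.4), tempfile(fileext = ".png")),
               "sum to 1")
  expect_error(plot_fraction_pie(c(A = 1.2, B = -0.2),
                                 tempfile(fileext = ".png")),
               "non-negative")
})
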