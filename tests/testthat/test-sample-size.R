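test_that("paired group-size kernels reproduce the example study", {
  nd <- n_diseased_paired(0.81, 0.90, psi_d = 0.09, alpha = 0.05, beta = 0.10)
  expect_equal(nd, 73.46, tolerance = 0.05 / 73.46)
  expect_equal(ceiling(nd), 74)
  nnd <- n_nondiseased_paired(0.66, 0.80, psi_nd = 0.14, alpha = 0.05,
                              beta = 0.10)
  expect_equal(nnd, 46.60, tolerance = 0.05 / 46.60)
  expect_equal(ceiling(nnd), 47)
})

test_that("paired kernel is symmetric in the two tests and matches a direct evaluation", {
  expect_equal(n_diseased_paired(0.90, 0.81, 0.09, 0.05, 0.10),
               n_diseased_paired(0.81, 0.90, 0.09, 0.05, 0.10))
  # independent re-evaluation of the closed form at the independence value
  se_c <- 0.7; se_e <- 0.8
  psi <- se_c + se_e - 2 * se_c * se_e   # 0.38
  z1 <- qnorm(0.975); z2 <- qnorm(0.8)
  rad <- psi^2 - 0.25 * (se_c - se_e)^2 * (3 + psi)
  oracle <- (z1 * psi + z2 * sqrt(rad))^2 / (psi * (se_c - se_e)^2)
  expect_equal(n_diseased_paired(se_c, se_e, psi, 0.05, 0.2), oracle,
               tolerance = 1e-12)
})

test_that("paired kernel rejects degenerate inputs with structured errors", {
  expect_error(n_diseased_paired(0.8, 0.8, 0.1, 0.05, 0.1), "sensitivity")
  expect_error(n_nondiseased_paired(0.7, 0.7, 0.1, 0.05, 0.1), "specificity")
  expect_error(n_diseased_paired(0.6, 0.9, 0.05, 0.05, 0.1), "radicand")
})

test_that("unpaired variance and kernel behave like the two-proportion formula", {
  expect_equal(unpaired_variance(0.5, 0.5), 0.5)
  expect_equal(unpaired_variance(0.81, 0.90), 0.2439)
  expect_equal(unpaired_variance(0, 1), 0)
  expect_equal(unpaired_variance(1, 1), 0)

  # closed-form oracle with pooled null variance
  se_c <- 0.8; se_e <- 0.9
  pbar <- (se_c + se_e) / 2
  oracle <- (qnorm(0.975) * sqrt(2 * pbar * (1 - pbar)) +
               qnorm(0.9) * sqrt(se_c * (1 - se_c) + se_e * (1 - se_e)))^2 /
    (se_c - se_e)^2
  expect_equal(n_diseased_unpaired(0.8, 0.9, 0.05, 0.1), oracle,
               tolerance = 1e-12)

  # monotone decreasing in the effect size at fixed average accuracy
  diffs <- c(0.05, 0.10, 0.15, 0.20)
  n <- vapply(diffs, function(d)
    n_diseased_unpaired(0.8 - d / 2, 0.8 + d / 2, 0.05, 0.1), numeric(1))
  expect_true(all(diff(n) < 0))
  expect_error(n_diseased_unpaired(0.8, 0.8, 0.05, 0.1), "zero difference")
})

test_that("discordance bounds match the maximal-dependence and independence edges", {
  expect_equal(unname(psi_bounds(0.5, 0.5)), c(0, 0.5))
  expect_equal(unname(psi_bounds(0.81, 0.90)), c(0.09, 0.252))
  expect_equal(psi_bounds(0.66, 0.80)[["lower"]], psi_min(0.66, 0.80))
  expect_equal(psi_min(0.81, 0.90), 0.09)
  expect_equal(psi_min(0.66, 0.80), 0.14)
  expect_equal(psi_min(0.7, 0.7), 0)
})

test_that("conventional calculation reproduces all printed example values", {
  res <- conventional_sample_size(example_spec(), example_params(),
                                  example_dep(),
                                  power_se = 0.9, power_sp = 0.9)
  expect_equal(res$n_diseased, 74L)
  expect_equal(res$n_nondiseased, 47L)
  expect_equal(ceiling(res$n_se_total - 1e-8), 157)
  expect_equal(ceiling(res$n_sp_total - 1e-8), 88)
  expect_equal(res$n_final, 157L)
})

test_that("optimal calculation reproduces the example study's planning sizes", {
  res <- optimal_sample_size(example_spec(), example_params(), example_dep())
  expect_equal(res$n_final, 133L)
  # re-estimated nuisance parameters of the example study
  res2 <- optimal_sample_size(example_spec(), example_params(prevalence = 0.44),
                              paired_dependence(0.11, 0.14))
  expect_equal(res2$n_final, 200L)
})

test_that("optimal size never exceeds the conventional size at the same split", {
  set.seed(99)
  for (k in 1:8) {
    setup <- random_paired_setup()
    spec <- design_spec("paired", 0.05, 0.8)
    opt <- optimal_sample_size(spec, setup$params, setup$dep)
    conv <- conventional_sample_size(spec, setup$params, setup$dep,
                                     power_se = opt$power_se,
                                     power_sp = opt$power_sp)
    expect_lte(opt$n_final, conv$n_final)
  }
})

test_that("minimal paired size is the example's internal-pilot size and a lower bound", {
  res <- minimal_sample_size_paired(example_spec(), example_params())
  expect_equal(res$n_final, 133L)
  expect_equal(res$method, "minimal")

  # monotone step check over a psi grid: minimal <= optimal everywhere,
  # and N is nondecreasing in both discordance proportions
  spec <- example_spec()
  params <- example_params()
  bd <- psi_bounds(params$se_c, params$se_e)
  bn <- psi_bounds(params$sp_c, params$sp_e)
  psis_d <- seq(bd[1], bd[2], length.out = 10)
  psis_nd <- seq(bn[1], bn[2], length.out = 10)
  nmat <- outer(psis_d, psis_nd, Vectorize(function(pd, pnd)
    optimal_sample_size(spec, params,
                        paired_dependence(pd, pnd))$n_se_total))
  expect_true(all(nmat >= res$n_se_total - 1e-6))
  expect_true(all(apply(nmat, 2, diff) >= -1e-9))
  expect_true(all(apply(nmat, 1, diff) >= -1e-9))
})

test_that("paired sizing requires a dependence object and admissible psi", {
  expect_error(conventional_sample_size(example_spec(), example_params()),
               "requires a paired_dependence")
  expect_error(optimal_sample_size(example_spec(), example_params(),
                                   paired_dependence(0.05, 0.14)),
               "below the admissible lower bound")
  expect_error(optimal_sample_size(design_spec("unpaired"), example_params(),
                                   example_dep()),
               "only meaningful in the paired design")
})
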