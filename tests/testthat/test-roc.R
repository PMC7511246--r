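test_that("ROC and AUC follow the exhaustive pair-count oracle", {
  # perfect separation
  rc <- roc_curve(c(0.01, 0.02, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rc$auc, 1)
  # worked case: positives {0.9, 0.8}, negatives {0.85, 0.1};
  # positive outranks negative in 1 of 4 pairs -> AUC 0.25
  rc2 <- roc_curve(c(0.9, 0.8, 0.85, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rc2$auc, 0.25)
  # random scores vs brute-force pair counting (with ties)
  set.seed(1)
  p <- round(runif(60), 2)
  tr <- rep(c(TRUE, FALSE), 30)
  rc3 <- roc_curve(p, tr)
  pos <- p[tr]; neg <- p[!tr]
  oracle <- mean(outer(pos, neg, function(a, b)
    (a < b) + 0.5 * (a == b)))
  expect_equal(rc3$auc, oracle, tolerance = 1e-12)
  # curves are monotone and end at (1, 1)
  expect_true(all(diff(rc3$fpr) >= 0) && all(diff(rc3$tpr) >= 0))
  expect_equal(c(tail(rc3$fpr, 1), tail(rc3$tpr, 1)), c(1, 1))
  expect_error(roc_curve(runif(5), rep(TRUE, 5)), "both truth classes")
})

test_that("permuted truth labels give chance-level AUC", {
  set.seed(2)
  p <- runif(2000)
  tr <- sample(rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(roc_curve(p, tr)$auc - 0.5), 0.03)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  p <- runif(300)^2
  tr <- runif(300) < 0.5 - 0.3 * p
  rc <- roc_curve(p, tr)
  ref <- pROC::auc(pROC::roc(response = tr, predictor = 1 - p,
                             quiet = TRUE, direction = "<"))
  expect_equal(rc$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("partial AUC normalisation reproduces the published pairings", {
  # a curve that is exactly linear up to the cut lets us place raw pAUC
  mk_curve <- function(height) {
    structure(list(fpr = c(0, 0.05, 1), tpr = c(0, height, 1)),
              class = "roc_curve")
  }
  # raw pAUC 0.016 over [0, 0.05] -> normalised 0.32
  expect_equal(partial_auc(mk_curve(0.64), 0.05, normalized = FALSE), 0.016)
  expect_equal(partial_auc(mk_curve(0.64), 0.05, normalized = TRUE), 0.32)
  # raw pAUC 0.010 -> normalised 0.20
  expect_equal(partial_auc(mk_curve(0.40), 0.05, normalized = TRUE), 0.20)
  # perfect classifier: raw 0.05, normalised 1
  perfect <- structure(list(fpr = c(0, 0, 1), tpr = c(0, 1, 1)),
                       class = "roc_curve")
  expect_equal(partial_auc(perfect, 0.05, normalized = FALSE), 0.05)
  expect_equal(partial_auc(perfect, 0.05), 1)
  # interpolation at the cut
  curve <- structure(list(fpr = c(0, 0.02, 0.1, 1), tpr = c(0, 0.3, 0.5, 1)),
                     class = "roc_curve")
  y_at_05 <- 0.3 + (0.5 - 0.3) * (0.05 - 0.02) / (0.1 - 0.02)
  manual <- 0.02 * 0.15 + 0.03 * (0.3 + y_at_05) / 2
  expect_equal(partial_auc(curve, 0.05, normalized = FALSE), manual,
               tolerance = 1e-12)
  expect_error(partial_auc(curve, 0), "fpr_max")
})

test_that("DeLong test matches placements, the reference implementation, and the null", {
  # identical scores -> zero difference, p = 1
  set.seed(4)
  p <- runif(50); tr <- rep(c(TRUE, FALSE), 25)
  d0 <- delong_test(p, p, tr)
  expect_equal(d0$p, 1)
  expect_equal(d0$auc_a, d0$auc_b)

  # tiny case vs explicit placement values
  pa <- c(0.1, 0.3, 0.7, 0.2, 0.9, 0.5)
  tr2 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  d <- delong_test(pa, rev(pa), tr2)
  pos <- -pa[tr2]; neg <- -pa[!tr2]
  v10 <- sapply(pos, function(x) mean(x > neg))
  expect_equal(d$auc_a, mean(v10), tolerance = 1e-12)

  skip_if_not_installed("pROC")
  set.seed(5)
  n <- 400
  tr3 <- rep(c(TRUE, FALSE), n / 2)
  pa3 <- ifelse(tr3, runif(n)^1.5, runif(n))
  pb3 <- ifelse(tr3, runif(n)^1.2, runif(n))
  mine <- delong_test(pa3, pb3, tr3)
  ra <- pROC::roc(tr3, 1 - pa3, quiet = TRUE, direction = "<")
  rb <- pROC::roc(tr3, 1 - pb3, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(mine$p, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("DeLong p-values are uniform when both classifiers are null", {
  set.seed(6)
  ps <- replicate(200, {
    tr <- rep(c(TRUE, FALSE), 100)
    delong_test(runif(200), runif(200), tr)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("bootstrap pAUC test is calibrated at the extremes", {
  set.seed(7)
  p <- runif(400); tr <- rep(c(TRUE, FALSE), 200)
  it <- rep(1:40, each = 10)
  same <- suppressWarnings(
    pauc_bootstrap_test(p, p, tr, iteration = it, n_boot = 120))
  expect_gt(same$p, 0.9)
  # reproducible given the seed
  a <- pauc_bootstrap_test(p, rev(p), tr, iteration = it, n_boot = 120,
                           seed = 3)
  b <- pauc_bootstrap_test(p, rev(p), tr, iteration = it, n_boot = 120,
                           seed = 3)
  expect_identical(a$p, b$p)
  expect_error(pauc_bootstrap_test(p, p, tr, n_boot = 50), "at least 100")
})

test_that("bootstrap pAUC test detects a large true gap", {
  set.seed(8)
  hits <- replicate(20, {
    tr <- rep(c(TRUE, FALSE), 250)
    # classifier A separates strongly below the 0.05 FPR range, B is null
    pa <- ifelse(tr, rbeta(500, 0.25, 6), runif(500))
    pb <- runif(500)
    it <- rep(1:50, each = 10)
    pauc_bootstrap_test(pa, pb, tr, iteration = it, n_boot = 150)$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("calibration curve reproduces direct counting", {
  # uniform p: near the identity
  set.seed(9)
  cal <- calibration_curve(runif(1e4))
  expect_lt(cal$max_deviation, 0.02)
  # point mass at 0.001: step from 0 to 1
  cal2 <- calibration_curve(rep(0.001, 200), grid = c(0.0005, 0.005, 0.5))
  expect_equal(cal2$fpr, c(0, 1, 1))
  # explicit 10-value oracle
  p10 <- c(0.01, 0.02, 0.03, 0.2, 0.3, 0.4, 0.5, 0.6, 0.9, 1.0)
  cal3 <- calibration_curve(p10, grid = seq(0.1, 1, by = 0.1))
  expect_equal(cal3$fpr, sapply(seq(0.1, 1, by = 0.1),
                                function(g) mean(p10 <= g)))
  expect_true(all(diff(cal3$fpr) >= 0))
})

test_that("one iteration emits 22 decisions per chromophore, deterministically", {
  pl <- pipeline_spec(condition = "rest", solver = "ols", cnr = 0)
  ns <- quick_noise(90)
  r1 <- run_iteration(pl, seed = 11, noise = ns, joint = TRUE)
  r2 <- run_iteration(pl, seed = 11, noise = ns, joint = TRUE)
  expect_identical(r1, r2)
  expect_equal(sum(r1$chromophore == "hbo"), 22)
  expect_equal(sum(r1$chromophore == "hbr"), 22)
  expect_equal(sum(r1$chromophore == "joint"), 22)
  expect_equal(sum(r1$truth[r1$chromophore == "hbo"]), 11)
  expect_true(all(r1$p >= 0 & r1$p <= 1))
})

test_that("the benchmark grid covers the 60 published pipeline combinations", {
  conds <- c("rest", "bh_random", "bh_locked")
  prefs <- c("none", "pca", "bpca", "ss_projection")
  solvers <- list(list(solver = "ols", ss_mode = "none"),
                  list(solver = "ols", ss_mode = "both"),
                  list(solver = "ar_irls", ss_mode = "none"),
                  list(solver = "ar_irls", ss_mode = "both"),
                  list(solver = "me_ar_irls", ss_mode = "both"))
  grid <- list()
  for (cd in conds) for (pf in prefs) for (sv in solvers)
    grid[[length(grid) + 1]] <-
      pipeline_spec(condition = cd, prefilter = pf,
                    solver = sv$solver, ss_mode = sv$ss_mode)
  expect_length(grid, 60)
  expect_length(unique(sapply(grid, function(g)
    paste(g$condition, g$prefilter, g$solver, g$ss_mode))), 60)
})

test_that("run_benchmark pools decisions and reports per-pipeline summaries", {
  ns <- quick_noise(90)
  pls <- list(pipeline_spec(condition = "rest", solver = "ols", cnr = 2),
              pipeline_spec(condition = "rest", solver = "ols", cnr = 0))
  b <- run_benchmark(pls, n_iterations = 2, master_seed = 5, noise = ns)
  expect_equal(nrow(b$summary), 4)          # 2 pipelines x 2 chromophores
  expect_equal(unique(b$summary$n_decisions), 44)
  expect_equal(b$n_failed, 0)
  b2 <- run_benchmark(pls, n_iterations = 2, master_seed = 5, noise = ns)
  expect_identical(b$summary, b2$summary)
  # strong injected response outranks the null pipeline
  a_cnr2 <- b$summary$auc[b$summary$pipeline == 1 &
                          b$summary$chromophore == "hbo"]
  a_cnr0 <- b$summary$auc[b$summary$pipeline == 2 &
                          b$summary$chromophore == "hbo"]
  expect_gt(a_cnr2, a_cnr0)
})
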