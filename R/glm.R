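#' Design matrix for the channel-wise GLM
#'
#' Bundles the task regressors and the optional SS nuisance block.  An
#' intercept is always added by the solvers and does not appear here.
#' Task and nuisance regressors are deliberately not orthogonalised
#' against each other: the SS traces are not gated by the task timing,
#' so their collinearity with the task block is weak, and
#' orthogonalising would silently reassign shared variance.
#'
#' @param xtask matrix of task regressors (see [build_task_design()]).
#' @param xshort optional nuisance matrix (see [build_ss_design()]).
#' @param fs sampling rate (Hz).
#' @return Object of class `design_matrix`.
#' @export
design_matrix <- function(xtask, xshort = NULL, fs) {
  xtask <- as.matrix(xtask)
  if (is.null(colnames(xtask)))
    colnames(xtask) <- paste0("task", seq_len(ncol(xtask)))
  if (any(apply(xtask, 2, function(x) all(x == 0))))
    stop("design contains an all-zero task column")
  if (!is.null(xshort)) {
    xshort <- as.matrix(xshort)
    if (nrow(xshort) != nrow(xtask))
      stop("xtask and xshort have different numbers of rows")
    if (is.null(colnames(xshort)))
      colnames(xshort) <- paste0("ss", seq_len(ncol(xshort)))
  }
  structure(list(xtask = xtask, xshort = xshort, fs = fs),
            class = "design_matrix")
}

full_design <- function(design) {
  x <- cbind(`(Intercept)` = 1, design$xtask, design$xshort)
  attr(x, "task_cols") <- 1L + seq_len(ncol(design$xtask))
  attr(x, "short_cols") <- if (is.null(design$xshort)) integer(0) else
    1L + ncol(design$xtask) + seq_len(ncol(design$xshort))
  x
}

## ---- internal solvers -----------------------------------------------------

# Tukey bisquare weights; scale is fixed while iterating.
bisquare_weights <- function(r, scale, c = 4.685) {
  u <- abs(r) / (c * scale)
  w <- (1 - pmin(u, 1)^2)^2
  pmax(w, .Machine$double.eps)      # keep weights in (0, 1]
}

# Iteratively reweighted least squares with Tukey bisquare psi.
# The last `n_fixed` rows (ridge-prior pseudo-observations) always
# keep weight 1 and are excluded from the scale estimate - they are
# exact constraints, not data that can be outlying.
# Returns coefficients, final weights, residuals and the robust scale.
irls_bisquare <- function(x, y, max_iter = 30, tol = 1e-6, n_fixed = 0L) {
  n_dat <- length(y) - n_fixed
  dat <- seq_len(n_dat)
  robust_weights <- function(beta) {
    r <- drop(y - x %*% beta)
    rd <- r[dat]
    s <- stats::median(abs(rd - stats::median(rd))) * 1.4826
    w <- rep(1, length(y))
    if (s > .Machine$double.eps) w[dat] <- bisquare_weights(rd, s)
    list(w = w, r = r, s = s)
  }
  fit <- stats::lm.fit(x, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  for (i in seq_len(max_iter)) {
    rw <- robust_weights(beta)
    if (rw$s <= .Machine$double.eps) break
    fitw <- stats::lm.wfit(x, y, rw$w)
    bnew <- fitw$coefficients
    bnew[is.na(bnew)] <- 0
    delta <- max(abs(bnew - beta)) / max(1e-12, max(abs(beta)))
    beta <- bnew
    if (delta < tol) break
  }
  rw <- robust_weights(beta)
  list(beta = beta, weights = rw$w, resid = rw$r, scale = rw$s)
}

# Apply the AR whitening filter e(t) = y(t) - sum(phi_k y(t-k)); the
# first length(phi) samples (incomplete history) are dropped.
ar_whiten <- function(x, phi) {
  x <- as.matrix(x)
  p <- length(phi)
  if (p == 0L) return(x)
  out <- stats::filter(x, c(1, -phi), method = "convolution", sides = 1)
  out <- as.matrix(out)[-seq_len(p), , drop = FALSE]
  out
}

# Inference shared by all solvers: classical (weighted) covariance on
# the final (possibly whitened) system.
glm_inference <- function(xw, yw, beta, w, task_cols, ridge_rows = 0L) {
  r <- drop(yw - xw %*% beta)
  rank <- qr(xw)$rank
  dof <- sum(w) - rank
  if (dof <= 0) stop("non-positive degrees of freedom")
  sigma2 <- sum(w * r^2) / dof
  xtwx <- crossprod(xw * sqrt(w))
  cov_beta <- tryCatch(solve(xtwx) * sigma2,
                       error = function(e) MASSless_ginv(xtwx) * sigma2)
  se <- sqrt(pmax(diag(cov_beta), 0))
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), df = dof)
  list(beta = beta, se = se, t = t, p = p, dof = dof, sigma2 = sigma2,
       cov = cov_beta, resid = r, weights = w)
}

# Moore-Penrose fallback for near-singular cross-products.
MASSless_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

## ---- OLS ------------------------------------------------------------------

#' Ordinary least squares GLM
#'
#' Classical per-channel least squares with Student-t inference,
#' assuming independent homoscedastic errors.  Included as the
#' reference solver: with serially correlated physiological noise its
#' nominal p-values are badly anti-conservative (the type-I error can
#' exceed 60% at p < 0.05), which the ROC harness quantifies.
#'
#' @param y time x channel matrix (one chromophore) or a
#'   [hemo_scan()] plus `chromophore`.
#' @param design a [design_matrix()].
#' @param chromophore which block of a `hemo_scan` to fit.
#' @return Object of class `glm_result`: per-channel data frame
#'   `stats` (one row per channel and task regressor: beta, se, t,
#'   dof, p) and a `details` list (covariance, residuals, weights, AR
#'   coefficients).
#' @export
ols_fit <- function(y, design, chromophore = "hbo") {
  y <- scan_matrix(y, chromophore)
  x <- full_design(design)
  task_cols <- attr(x, "task_cols")
  if (nrow(y) <= ncol(x))
    stop("more regressors than time points")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop_cols <- colnames(x)[qx$pivot[-seq_len(qx$rank)]]
    stop("design is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  res <- lapply(seq_len(ncol(y)), function(j) {
    beta <- qr.coef(qx, y[, j])
    glm_inference(x, y[, j], beta, rep(1, nrow(x)), task_cols)
  })
  as_glm_result(res, x, design, solver = "ols")
}

## ---- AR-IRLS --------------------------------------------------------------

#' Robust autoregressively prewhitened GLM (AR-IRLS)
#'
#' Per channel, iterates: (a) robust regression (Tukey bisquare,
#' tuning constant 4.685, MAD scale); (b) an autoregressive fit to the
#' residuals with the order chosen by AIC up to `max_ar_order`;
#' (c) application of the AR whitening filter to both the data and the
#' design, and a robust re-solve on the whitened system.  Iteration
#' stops when the coefficients stabilise (relative change < `tol`) or
#' after `max_iter` passes.  Inference is classical-weighted on the
#' whitened model with effective degrees of freedom
#' `sum(robust weights) - rank(X)`.
#'
#' @inheritParams ols_fit
#' @param max_ar_order maximum AR order searched by AIC; default
#'   `ceiling(4 * fs)` (about 4 s of history).
#' @param max_iter,tol outer-loop convergence controls.
#' @return A `glm_result`; channels that failed to stabilise are
#'   flagged in `details[[j]]$converged` and a warning is raised.
#' @export
ar_irls_fit <- function(y, design, chromophore = "hbo",
                        max_ar_order = NULL, max_iter = 10, tol = 1e-4) {
  y <- scan_matrix(y, chromophore)
  x <- full_design(design)
  max_ar_order <- max_ar_order %||% ceiling(4 * design$fs)
  if (nrow(y) <= max_ar_order + ncol(x))
    stop("scan too short for the requested AR order and design size")
  res <- lapply(seq_len(ncol(y)), function(j)
    ar_irls_channel(x, y[, j], max_ar_order, max_iter, tol))
  if (!all(vapply(res, `[[`, TRUE, "converged")))
    warning("AR-IRLS did not converge in ",
            sum(!vapply(res, `[[`, TRUE, "converged")), " channel(s); ",
            "last iterate returned")
  as_glm_result(res, x, design, solver = "ar_irls")
}

ar_irls_channel <- function(x, y, max_ar_order, max_iter, tol,
                            ridge = NULL) {
  rob <- irls_bisquare(x, y)
  beta <- rob$beta
  phi <- numeric(0)
  converged <- FALSE
  fit <- NULL
  for (i in seq_len(max_iter)) {
    r <- drop(y - x %*% beta)
    arfit <- tryCatch(
      stats::ar(r, aic = TRUE, order.max = max_ar_order, method = "yule-walker",
                demean = TRUE),
      error = function(e) NULL)
    phi <- if (is.null(arfit)) numeric(0) else arfit$ar
    yw <- drop(ar_whiten(y, phi))
    xw <- ar_whiten(x, phi)
    n_fixed <- 0L
    if (!is.null(ridge)) {
      xw <- rbind(xw, ridge$rows)
      yw <- c(yw, numeric(nrow(ridge$rows)))
      n_fixed <- nrow(ridge$rows)
    }
    fit <- irls_bisquare(xw, yw, n_fixed = n_fixed)
    delta <- max(abs(fit$beta - beta)) / max(1e-12, max(abs(beta)))
    beta <- fit$beta
    if (delta < tol) { converged <- TRUE; break }
  }
  # Inference on the whitened (possibly ridge-augmented) system.
  # The coefficient covariance uses the standard M-estimation
  # correction kappa = s^2 sum(psi(u)^2)/(n - k) / mean(psi'(u))^2,
  # which is Fisher-consistent under Gaussian noise (the naive
  # weighted residual variance underestimates sigma^2 for bisquare
  # weights and would overstate significance).
  yw <- drop(ar_whiten(y, phi))
  xw <- ar_whiten(x, phi)
  n_w <- length(yw)
  n_aug <- 0L
  if (!is.null(ridge)) {
    n_aug <- nrow(ridge$rows)
    xw <- rbind(xw, ridge$rows)
    yw <- c(yw, numeric(n_aug))
  }
  w <- fit$weights
  w_eff <- w
  if (n_aug > 0) w_eff[seq(n_w + 1, n_w + n_aug)] <- 0
  rank <- qr(xw)$rank
  dof <- sum(w_eff) - rank
  if (dof <= 0) stop("non-positive degrees of freedom after whitening")
  r <- drop(yw - xw %*% beta)
  rdat <- r[seq_len(n_w)]          # data rows only (no prior rows)
  s <- fit$scale
  if (s <= .Machine$double.eps) {
    sigma2 <- sum(rdat^2) / (n_w - rank)
  } else {
    cc <- 4.685
    u <- rdat / s
    inb <- abs(u) <= cc
    psi <- ifelse(inb, u * (1 - (u / cc)^2)^2, 0)
    psip <- ifelse(inb, (1 - (u / cc)^2) * (1 - 5 * (u / cc)^2), 0)
    sigma2 <- (s^2 * sum(psi^2) / (n_w - rank)) / mean(psip)^2
  }
  xtx <- crossprod(xw)
  cov_beta <- tryCatch(solve(xtx) * sigma2,
                       error = function(e) MASSless_ginv(xtx) * sigma2)
  se <- sqrt(pmax(diag(cov_beta), 0))
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = dof)
  list(beta = beta, se = se, t = tval, p = p, dof = dof, sigma2 = sigma2,
       cov = cov_beta, resid = r, weights = w, ar = phi,
       converged = converged)
}

## ---- mixed-effects AR-IRLS ------------------------------------------------

#' Mixed-effects AR-IRLS with pooled SS variance
#'
#' Treats the SS regressor coefficients as random effects drawn from a
#' zero-mean normal distribution whose scale `sigma` is shared by all
#' channels of the probe.  The model is solved by expectation-
#' maximisation: (i) with the current `sigma`, each channel is fit by
#' [ar_irls_fit()]'s inner solver with a ridge prior `1/sigma` on the
#' SS coefficients only (task coefficients are never penalised;
#' `sigma = Inf`, the starting value, means no penalty); (ii) `sigma`
#' is re-estimated as `1.4826 * MAD` (median absolute deviation, which
#' keeps the estimate centred on zero) of all SS coefficients pooled
#' across channels; (iii) repeat until `sigma` stabilises.  When the
#' superficial physiology is genuinely global the pooled distribution
#' is narrow and estimates borrow strength across channels; when it is
#' heterogeneous, `sigma` stays broad and the prior is non-informative.
#'
#' @inheritParams ar_irls_fit
#' @param max_outer,sigma_tol outer EM controls.
#' @details `design` may also be a list of [design_matrix()]s, one per
#'   channel, for the nearest-n analyses where each LD channel carries
#'   its own set of SS regressors; `sigma` is still pooled across the
#'   whole probe.
#' @return A `glm_result` whose `me_state` element records the pooled
#'   `sigma`, iteration count and convergence flag.
#' @export
me_ar_irls_fit <- function(y, design, chromophore = "hbo",
                           max_ar_order = NULL, max_iter = 10, tol = 1e-4,
                           max_outer = 20, sigma_tol = 1e-3) {
  y <- scan_matrix(y, chromophore)
  designs <- if (inherits(design, "design_matrix"))
    rep(list(design), ncol(y)) else design
  if (length(designs) != ncol(y))
    stop("need one design (or one per channel); got ", length(designs))
  if (ncol(y) < 2L)
    stop("the mixed-effects model needs at least two channels")
  # Put all SS columns on a common (unit-variance) scale so that the
  # pooled prior on their coefficients is meaningful; this is a pure
  # reparameterisation and leaves the task estimates untouched.
  xs <- lapply(designs, function(d) {
    if (is.null(d$xshort) || ncol(d$xshort) < 2L)
      stop("the mixed-effects model needs at least two SS regressors")
    zsd <- apply(d$xshort, 2, stats::sd)
    if (any(zsd == 0)) stop("constant SS regressor column")
    full_design(design_matrix(d$xtask, sweep(d$xshort, 2, zsd, "/"),
                              fs = d$fs))
  })
  max_ar_order <- max_ar_order %||% ceiling(4 * designs[[1]]$fs)
  sigma <- Inf
  res <- NULL
  converged <- FALSE
  iters <- 0L
  sigma_floor <- 1e-8 * stats::sd(y)
  for (it in seq_len(max_outer)) {
    iters <- it
    res <- lapply(seq_len(ncol(y)), function(j) {
      x <- xs[[j]]
      sc <- attr(x, "short_cols")
      ridge <- if (is.finite(sigma)) {
        # variance-weighted prior: rows scaled by the channel's residual
        # scale so the penalty is (sigma_eps / sigma) per SS coefficient
        s_eps <- sqrt(res[[j]]$sigma2)
        rows <- matrix(0, length(sc), ncol(x))
        rows[cbind(seq_along(sc), sc)] <- s_eps / sigma
        list(rows = rows)
      } else NULL
      ar_irls_channel(x, y[, j], max_ar_order, max_iter, tol,
                      ridge = ridge)
    })
    gam <- unlist(lapply(seq_along(res), function(j)
      res[[j]]$beta[attr(xs[[j]], "short_cols")]))
    # E-step variance update: robust spread of the point estimates
    # (1.4826 * median absolute deviation, which keeps the estimate
    # centred on zero) plus the mean posterior variance of the
    # coefficients.  Omitting the posterior-variance term (plugging in
    # shrunken point estimates only) makes sigma spiral to zero.
    pv <- unlist(lapply(seq_along(res), function(j)
      diag(res[[j]]$cov)[attr(xs[[j]], "short_cols")]))
    mad_part <- 1.4826 * stats::median(abs(gam - stats::median(gam)))
    sigma_new <- sqrt(mad_part^2 + mean(pmax(pv, 0)))
    if (sigma_new < sigma_floor) {
      warning("pooled SS coefficient scale collapsed; clamped to floor")
      sigma_new <- sigma_floor
    }
    if (is.finite(sigma) &&
        abs(sigma_new - sigma) / sigma < sigma_tol) {
      sigma <- sigma_new
      converged <- TRUE
      break
    }
    sigma <- sigma_new
  }
  out <- as_glm_result(res, xs[[1]], designs[[1]], solver = "me_ar_irls")
  out$me_state <- list(sigma = sigma, iterations = iters,
                       converged = converged)
  out
}

## ---- joint test -----------------------------------------------------------

#' Hotelling T-squared joint test of HbO2 and Hb
#'
#' Combines the per-chromophore task estimates of one channel into a
#' joint two-dimensional test: `T2 = b' C^-1 b` with
#' `b = (beta_HbO2, beta_Hb)` and `C` their covariance (the two fits
#' are independent, so `C` is diagonal).  Significance uses the F
#' transform `F = T2 (nu - 1) / (2 nu) ~ F(2, nu - 1)` with `nu` the
#' smaller of the two residual degrees of freedom.
#'
#' @param res_hbo,res_hbr `glm_result`s from the same design, one per
#'   chromophore.
#' @param task which task column to test (name or index).
#' @return Data frame: channel, `t2`, `p`.
#' @export
hotelling_joint <- function(res_hbo, res_hbr, task = 1L) {
  s1 <- res_hbo$stats; s2 <- res_hbr$stats
  if (!identical(dim(s1), dim(s2)))
    stop("results do not come from the same design/channels")
  tn <- unique(s1$term)[task]
  a <- s1[s1$term == tn, ]; b <- s2[s2$term == tn, ]
  t2 <- numeric(nrow(a)); p <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    C <- diag(c(a$se[i]^2, b$se[i]^2))
    if (any(diag(C) <= 0)) stop("singular covariance in channel ", i)
    bb <- c(a$beta[i], b$beta[i])
    t2[i] <- drop(bb %*% solve(C, bb))
    nu <- min(a$dof[i], b$dof[i])
    f <- t2[i] * (nu - 1) / (2 * nu)
    p[i] <- stats::pf(f, 2, nu - 1, lower.tail = FALSE)
  }
  data.frame(channel = a$channel, t2 = t2, p = p)
}

## ---- result assembly ------------------------------------------------------

scan_matrix <- function(y, chromophore) {
  if (inherits(y, "hemo_scan")) y[[chromophore]] else as.matrix(y)
}

as_glm_result <- function(res, x, design, solver) {
  task_cols <- attr(x, "task_cols")
  short_cols <- attr(x, "short_cols")
  stats_df <- do.call(rbind, lapply(seq_along(res), function(j) {
    r <- res[[j]]
    data.frame(channel = j,
               term = colnames(x)[task_cols],
               beta = r$beta[task_cols],
               se = r$se[task_cols],
               t = r$t[task_cols],
               dof = r$dof,
               p = r$p[task_cols],
               row.names = NULL)
  }))
  beta_short <- if (length(short_cols))
    t(vapply(res, function(r) r$beta[short_cols],
             numeric(length(short_cols)))) else NULL
  structure(list(stats = stats_df, beta_short = beta_short,
                 details = res, solver = solver,
                 terms = colnames(x)),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat("<glm_result> solver=", x$solver, ", ",
      length(x$details), " channels\n", sep = "")
  print(utils::head(x$stats, 8))
  if (nrow(x$stats) > 8) cat("...\n")
  invisible(x)
}

#' Tidy per-channel GLM table
#'
#' @param res a `glm_result`.
#' @param chromophore label to attach.
#' @return Data frame channel/chromophore/term/beta/se/t/dof/p.
#' @export
tidy_glm <- function(res, chromophore = NA_character_) {
  out <- res$stats
  out$chromophore <- chromophore
  out$solver <- res$solver
  out[, c("channel", "chromophore", "term", "beta", "se", "t", "dof",
          "p", "solver")]
}
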