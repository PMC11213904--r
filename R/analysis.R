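## First-level GLM analysis, quality metrics, ROI logic and the
## winner-take-all eccentricity preference map.

#' Canonical double-gamma hemodynamic response function
#'
#' The standard double-gamma kernel: a response gamma peaking at 5 s
#' (shape 6, rate 1) minus an undershoot gamma (shape 16, rate 1) at 1/6
#' amplitude, scaled to unit peak. `h(0) = 0` and the tail decays to zero
#' by ~32 s.
#'
#' @param t Time in seconds (>= 0).
#' @param peak_shape,undershoot_shape,rate,undershoot_ratio Gamma
#'   parameters of the kernel.
#' @return Amplitude at `t` (unit peak).
#' @export
canonical_hrf <- function(t, peak_shape = 6, undershoot_shape = 16,
                          rate = 1, undershoot_ratio = 6) {
  if (any(t < 0)) stop("t must be non-negative")
  h <- stats::dgamma(t, peak_shape, rate) -
    stats::dgamma(t, undershoot_shape, rate) / undershoot_ratio
  tg <- seq(0, 32, by = 0.01)
  hmax <- max(stats::dgamma(tg, peak_shape, rate) -
                stats::dgamma(tg, undershoot_shape, rate) / undershoot_ratio)
  h / hmax
}

#' Build the GLM design matrix
#'
#' One column per condition (HRF-convolved boxcar built on a supersampled
#' time grid and sampled at scan onsets), six motion nuisance columns when
#' supplied, and an intercept. The convolution kernel is normalised to
#' unit integral so that a sustained block regressor plateaus at 1 and the
#' condition betas read directly in the units of the data (percent signal
#' change after [fit_glm()] scaling). Zero-variance nuisance columns are
#' dropped with a warning; rank deficiency among the remaining columns is
#' an error.
#'
#' @param events Data frame with `onset`, `duration`, `trial_type`
#'   (fixation/rest rows are ignored as baseline).
#' @param TR Repetition time (s).
#' @param n_scans Number of volumes.
#' @param motion Optional n_scans x 6 matrix of motion parameters.
#' @param dt Supersampling resolution (s) for the convolution grid.
#' @param drift_order Order of Legendre-polynomial drift regressors
#'   (0 disables); order 2 mirrors the linear/slow trend removal the
#'   preprocessing conventions assume.
#' @param baseline_labels Labels treated as unmodelled baseline.
#' @return Matrix with attributes `conditions` (condition column names)
#'   and `kernel` (kernel id string).
#' @export
build_design_matrix <- function(events, TR, n_scans, motion = NULL,
                                dt = 0.1, drift_order = 2,
                                baseline_labels = c("fixation", "rest")) {
  if (any(events$onset + events$duration > n_scans * TR + 1e-6))
    stop("events extend beyond the run")
  conds <- sort(setdiff(unique(events$trial_type), baseline_labels))
  grid_n <- ceiling(n_scans * TR / dt)
  hrf <- canonical_hrf(seq(0, 32, by = dt))
  hrf <- hrf / sum(hrf * dt)             # unit integral: block plateau = 1
  scan_idx <- pmax(1, pmin(grid_n, round(((seq_len(n_scans) - 1) * TR) / dt) + 1))
  X <- sapply(conds, function(cn) {
    box <- numeric(grid_n)
    ev <- events[events$trial_type == cn, ]
    for (i in seq_len(nrow(ev))) {
      a <- floor(ev$onset[i] / dt) + 1
      b <- min(grid_n, ceiling((ev$onset[i] + ev$duration[i]) / dt))
      box[a:b] <- 1
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(grid_n)] * dt
    conv[scan_idx]
  })
  colnames(X) <- conds
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_scans) stop("motion rows must equal n_scans")
    keep <- apply(motion, 2, stats::var) > 0
    if (!all(keep)) warning(sum(!keep), " zero-variance motion column(s) dropped")
    if (any(keep)) {
      mo <- scale(motion[, keep, drop = FALSE])
      colnames(mo) <- paste0("motion", which(keep))
      X <- cbind(X, mo)
    }
  }
  if (drift_order > 0) {
    L <- legendre_basis(n_scans, drift_order)[, -1, drop = FALSE]
    colnames(L) <- paste0("drift", seq_len(ncol(L)))
    X <- cbind(X, L)
  }
  X <- cbind(X, intercept = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  attr(X, "conditions") <- conds
  attr(X, "kernel") <- "double-gamma(6,16,1/6)"
  attr(X, "TR") <- TR
  X
}

#' Fit the voxel-wise GLM with PSC scaling and AR(1) prewhitening
#'
#' Each voxel is fit by ordinary least squares and -- when `prewhiten` is
#' on -- refit after an AR(1) (Cochrane-Orcutt) transform with the lag-1
#' autocorrelation estimated from the OLS residuals (one iteration).
#' Betas are then expressed in percent signal change by referencing the
#' voxel's fitted baseline (the intercept): `beta_psc = 100 * beta / b0`,
#' which recovers planted amplitudes exactly in the noiseless case.
#' Voxels with near-zero mean (or non-positive baseline) are masked out
#' and counted.
#'
#' @param bold Voxels x time numeric matrix, or an object with a `$data`
#'   matrix (see [synth_bold()]).
#' @param X Design matrix from [build_design_matrix()].
#' @param prewhiten Apply AR(1) prewhitening.
#' @return An object of class `ff_glm`: `betas` (voxels x regressors,
#'   PSC), `sigma2`, `rho`, `df`, `cov_unscaled` (regressors x regressors
#'   x voxels), `conditions`, `mask` (voxels retained), `n_masked`.
#' @export
fit_glm <- function(bold, X, prewhiten = TRUE) {
  Y <- if (is.list(bold)) bold$data else bold
  if (ncol(Y) != nrow(X)) stop("time dimension of bold and design disagree")
  V <- nrow(Y); P <- ncol(X); n <- nrow(X)
  mu <- rowMeans(Y)
  mask <- is.finite(mu) & abs(mu) > 1e-8 * max(abs(mu), 1)

  betas <- matrix(NA_real_, V, P, dimnames = list(NULL, colnames(X)))
  sigma2 <- rep(NA_real_, V); rho <- rep(NA_real_, V)
  cov_u <- array(NA_real_, c(P, P, V))
  df <- n - P
  icol <- which(colnames(X) == "intercept")

  qrX <- qr(X)
  B0 <- t(qr.coef(qrX, t(Y[mask, , drop = FALSE])))
  E0 <- Y[mask, , drop = FALSE] - B0 %*% t(X)
  rss0 <- rowSums(E0^2)
  r1 <- rowSums(E0[, -1, drop = FALSE] * E0[, -n, drop = FALSE])
  # voxels with (numerically) zero residual are treated as white
  rho_v <- ifelse(rss0 > 1e-12 * n * pmax(1, mu[mask]^2), r1 / rss0, 0)
  rho_v <- pmin(0.95, pmax(-0.95, rho_v))
  if (!prewhiten) rho_v[] <- 0

  xtxinv0 <- chol2inv(chol(crossprod(X)))
  vi <- which(mask)
  for (k in seq_along(vi)) {
    v <- vi[k]
    r <- rho_v[k]
    if (abs(r) < 1e-8) {
      betas[v, ] <- B0[k, ]
      sigma2[v] <- rss0[k] / df
      rho[v] <- 0
      cov_u[, , v] <- xtxinv0
    } else {
      w1 <- sqrt(1 - r^2)
      Xw <- rbind(X[1, ] * w1, X[-1, , drop = FALSE] - r * X[-n, , drop = FALSE])
      yw <- c(Y[v, 1] * w1, Y[v, -1] - r * Y[v, -n])
      fitv <- stats::lm.fit(Xw, yw)
      betas[v, ] <- fitv$coefficients
      sigma2[v] <- sum(fitv$residuals^2) / df
      rho[v] <- r
      R <- qr.R(fitv$qr)
      cov_u[, , v] <- chol2inv(R)
    }
  }

  # percent-signal-change units: reference the fitted baseline
  b0 <- betas[, icol]
  bad <- mask & (!is.finite(b0) | b0 <= 0)
  mask[bad] <- FALSE
  betas[bad, ] <- NA; sigma2[bad] <- NA; rho[bad] <- NA
  sc <- ifelse(mask, 100 / b0, NA)
  betas <- betas * sc
  sigma2 <- sigma2 * sc^2
  n_masked <- sum(!mask)
  structure(list(betas = betas, sigma2 = sigma2, rho = rho, df = df,
                 cov_unscaled = cov_u,
                 conditions = attr(X, "conditions"),
                 mask = mask, n_masked = n_masked,
                 kernel = attr(X, "kernel")),
            class = "ff_glm")
}

#' @export
print.ff_glm <- function(x, ...) {
  cat(sprintf("GLM fit: %d voxels (%d masked out), %d regressors, df %d\n",
              length(x$sigma2), x$n_masked, ncol(x$betas), x$df))
  cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = ", ")))
  cat(sprintf("  median AR(1) rho: %.2f; kernel %s\n",
              stats::median(x$rho, na.rm = TRUE), x$kernel))
  invisible(x)
}

#' @export
coef.ff_glm <- function(object, conditions_only = TRUE, ...) {
  if (conditions_only) object$betas[, object$conditions, drop = FALSE]
  else object$betas
}

# expand a condition-space contrast to the full regressor space
expand_contrast <- function(fit, contrast) {
  full <- stats::setNames(numeric(ncol(fit$betas)), colnames(fit$betas))
  if (!is.null(names(contrast))) {
    if (!all(names(contrast) %in% names(full)))
      stop("unknown condition in contrast: ",
           paste(setdiff(names(contrast), names(full)), collapse = ", "))
    full[names(contrast)] <- contrast
  } else {
    if (length(contrast) != length(fit$conditions))
      stop("unnamed contrast must have one entry per condition")
    full[fit$conditions] <- contrast
  }
  if (all(full == 0)) stop("contrast vector is all zero")
  full
}

#' Voxel-wise t statistics for a condition contrast
#'
#' @param fit An [fit_glm()] result.
#' @param contrast Numeric contrast over conditions: named (e.g.
#'   `c(postcard_scene = 1, face = -1)`) or unnamed of length
#'   `length(fit$conditions)`.
#' @return A list: `t` (per voxel), `df`, `effect` (contrast of betas).
#' @export
contrast_tmap <- function(fit, contrast) {
  cv <- expand_contrast(fit, contrast)
  eff <- as.vector(fit$betas %*% cv)
  V <- length(fit$sigma2)
  se <- vapply(seq_len(V), function(v) {
    if (!fit$mask[v]) return(NA_real_)
    sqrt(fit$sigma2[v] * drop(t(cv) %*% fit$cov_unscaled[, , v] %*% cv))
  }, numeric(1))
  list(t = eff / se, df = fit$df, effect = eff)
}

#' Conjunction ROI mask over pairwise contrasts
#'
#' A voxel enters the mask only if every pairwise contrast
#' `target - other` exceeds the one-sided threshold at `alpha`
#' (minimum-statistic conjunction), e.g. far-periphery > each other
#' eccentricity band.
#'
#' @param fit An [fit_glm()] result.
#' @param target Condition name.
#' @param others Character vector of comparison conditions.
#' @param alpha One-sided uncorrected voxel threshold.
#' @return Logical vector (voxels); attribute `n` gives the voxel count.
#'   Empty conjunctions warn.
#' @export
conjunction_mask <- function(fit, target, others, alpha = 1e-4) {
  if (!length(others)) stop("need at least one comparison condition")
  tcrit <- stats::qt(1 - alpha, fit$df)
  tmin <- rep(Inf, length(fit$sigma2))
  for (oth in others) {
    ct <- stats::setNames(c(1, -1), c(target, oth))
    tmin <- pmin(tmin, contrast_tmap(fit, ct)$t)
  }
  mask <- !is.na(tmin) & tmin > tcrit
  if (!any(mask)) warning("conjunction mask is empty")
  attr(mask, "n") <- sum(mask)
  mask
}

#' Winner-take-all preference map
#'
#' For each voxel the condition with the highest (group-average) response
#' is the preferred condition; preference strength is the margin between
#' the best and second-best responses. Ties resolve to the lowest
#' condition index (strength 0 for an exact tie).
#'
#' @param condition_means Voxels x conditions matrix of responses (e.g.
#'   betas averaged over subjects).
#' @return A list of class `ff_prefmap`: `index` (1-based preferred
#'   condition), `strength` (top1 - top2, >= 0), `labels`.
#' @export
preference_map <- function(condition_means) {
  m <- as.matrix(condition_means)
  if (ncol(m) < 2) stop("need at least two conditions")
  idx <- max.col(m, ties.method = "first")
  top1 <- m[cbind(seq_len(nrow(m)), idx)]
  m2 <- m
  m2[cbind(seq_len(nrow(m)), idx)] <- -Inf
  top2 <- m2[cbind(seq_len(nrow(m)), max.col(m2, ties.method = "first"))]
  structure(list(index = idx, strength = top1 - top2,
                 labels = colnames(m)),
            class = "ff_prefmap")
}

#' @export
print.ff_prefmap <- function(x, ...) {
  cat(sprintf("Preference map: %d voxels, %d conditions\n",
              length(x$index), max(x$index)))
  print(table(preferred = if (!is.null(x$labels)) x$labels[x$index] else x$index))
  invisible(x)
}

#' Temporal signal-to-noise ratio
#'
#' Voxel-wise mean over standard deviation of the time course. Constant
#' series give infinite tSNR and are reported via the `n_constant`
#' attribute.
#'
#' @param bold Voxels x time matrix (or an object with `$data`).
#' @return Numeric vector of tSNR values with attribute `n_constant`.
#' @export
compute_tsnr <- function(bold) {
  Y <- if (is.list(bold)) bold$data else bold
  if (ncol(Y) < 2) stop("need at least two time points")
  mu <- rowMeans(Y)
  sd_ <- apply(Y, 1, stats::sd)
  out <- ifelse(sd_ > 0, mu / sd_, Inf)
  attr(out, "n_constant") <- sum(sd_ == 0)
  out
}

#' Remove one ROI's overlap from another
#'
#' @param roi_a,roi_b Logical vectors/arrays on the same grid.
#' @return `roi_a` minus the intersection, with attribute
#'   `overlap_fraction` (share of `roi_a` voxels removed).
#' @export
subtract_overlap <- function(roi_a, roi_b) {
  if (!identical(dim(roi_a), dim(roi_b)) || length(roi_a) != length(roi_b))
    stop("ROI grids do not match")
  inter <- roi_a & roi_b
  out <- roi_a & !roi_b
  attr(out, "overlap_fraction") <-
    if (sum(roi_a) > 0) sum(inter) / sum(roi_a) else 0
  out
}

#' Two-way ANOVA on ROI betas
#'
#' Fixed-effects size x content ANOVA on per-subject condition means
#' (balanced cells required), returning F, p and eta squared
#' (`SS_effect / SS_total`) per effect.
#'
#' @param data Data frame with columns `beta` and the two factors.
#' @param factors Names of the two factor columns.
#' @return Data frame with rows size, content, interaction.
#' @export
roi_anova <- function(data, factors = c("size", "content")) {
  f1 <- factor(data[[factors[1]]]); f2 <- factor(data[[factors[2]]])
  if (length(unique(table(f1, f2))) != 1)
    stop("unbalanced design: cell counts differ")
  if (stats::var(data$beta) == 0)
    stop("zero-variance data: F undefined")
  fit <- stats::aov(data$beta ~ f1 * f2)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  data.frame(effect = c(factors, "interaction"),
             F = tab[["F value"]][1:3],
             p = tab[["Pr(>F)"]][1:3],
             df1 = tab[["Df"]][1:3],
             df2 = tab[["Df"]][4],
             etaSq = ss[1:3] / sum(ss))
}
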