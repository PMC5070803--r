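#' Extract a normalized FRAP recovery curve
#'
#' ROI mean intensity, background-subtracted and double-normalized: divided
#' by the (background-subtracted) mean of a reference region to correct for
#' acquisition photobleaching of the whole cell, then rescaled so the
#' pre-bleach average equals 1. Time is measured from the bleach frame.
#'
#' @param stack An [image_stack()].
#' @param roi Bleached region, a [circular_roi()].
#' @param background_region Logical mask (or [circular_roi()]) of a region
#'   outside the cell.
#' @param reference_region Logical mask (or [circular_roi()]) of an unbleached
#'   region inside the cell, disjoint from `roi`.
#' @param bleach_frame Index of the first bleached frame.
#' @return A `recovery_curve`: a tibble with `time_s` (0 at the bleach frame)
#'   and `intensity`, carrying attributes `bleach_frame` and `f0` (the bleach
#'   floor, the minimum of the 3-frame-smoothed post-bleach trace).
#' @export
extract_recovery <- function(stack, roi, background_region, reference_region,
                             bleach_frame) {
  stopifnot(inherits(stack, "image_stack"))
  if (bleach_frame < 2L || bleach_frame > n_frames(stack)) {
    stop("`bleach_frame` must lie within the stack (with pre-bleach frames before it)",
         call. = FALSE)
  }
  dimf <- dim(stack$data)[2:3]
  as_mask <- function(m) {
    if (inherits(m, "circular_roi")) roi_mask(m, dimf, stack$pixel_size) else m
  }
  m_roi <- as_mask(roi); m_bg <- as_mask(background_region)
  m_ref <- as_mask(reference_region)
  if (any(m_ref & m_roi) || any(m_bg & m_roi)) {
    stop("background/reference regions must be disjoint from the ROI", call. = FALSE)
  }
  roi_t <- ref_t <- bg_t <- numeric(n_frames(stack))
  for (t in seq_len(n_frames(stack))) {
    fr <- stack_frame(stack, t)
    roi_t[t] <- mean(fr[m_roi]); ref_t[t] <- mean(fr[m_ref])
    bg_t[t] <- mean(fr[m_bg])
  }
  if (mean(ref_t - bg_t) <= 0) {
    stop("reference region is not brighter than background: invalid normalization",
         call. = FALSE)
  }
  ratio <- (roi_t - bg_t) / (ref_t - bg_t)
  pre <- mean(ratio[seq_len(bleach_frame - 1L)])
  norm <- ratio / pre
  time_s <- (seq_len(n_frames(stack)) - bleach_frame) * stack$frame_interval
  post <- norm[time_s >= 0]
  sm <- if (length(post) >= 3L) stats::filter(post, rep(1 / 3, 3L)) else post
  f0 <- min(sm, na.rm = TRUE)
  out <- tibble::tibble(time_s = time_s, intensity = norm)
  class(out) <- c("recovery_curve", class(out))
  attr(out, "bleach_frame") <- as.integer(bleach_frame)
  attr(out, "f0") <- f0
  out
}

# model: F(t) = F0 + A1 (1 - exp(-t/tau1)) + A2 (1 - exp(-t/tau2))
.frap_model <- function(t, f0, a1, tau1, a2, tau2) {
  f0 + a1 * (1 - exp(-t / tau1)) + a2 * (1 - exp(-t / tau2))
}

#' Fit the two-exponential FRAP recovery model
#'
#' Least-squares fit of
#' `F(t) = F0 + A1 (1 - exp(-t/tau1)) + A2 (1 - exp(-t/tau2))` to the
#' post-bleach samples, a reaction-diffusion-motivated two-timescale model.
#' Fitting uses bounded Levenberg-Marquardt with multiple starts spanning
#' several decades of time constants; the best residual is kept and
#' `tau1 <= tau2` is enforced by relabelling. The mobile fraction is
#' normalized by the bleach depth, `(A1 + A2) / (1 - F0)` (the plateau
#' recovered relative to what was bleached); the unnormalized plateau gain
#' `A1 + A2` is also reported. The half time solves
#' `F(t) = F0 + (A1 + A2)/2` on the fitted curve.
#'
#' @param curve A `recovery_curve` from [extract_recovery()], or any tibble
#'   with `time_s` and `intensity` (time 0 = bleach).
#' @param n_starts Number of multi-start time-constant pairs (>= 5).
#' @return A `frap_fit` object; see [tidy.frap_fit()] and
#'   [glance.frap_fit()].
#' @export
fit_two_exp <- function(curve, n_starts = 7L) {
  stopifnot(all(c("time_s", "intensity") %in% names(curve)))
  post <- curve[curve$time_s >= 0, ]
  if (nrow(post) < 10L) stop("need at least 10 post-bleach samples", call. = FALSE)
  t <- post$time_s; y <- post$intensity
  f0_start <- max(min(y), 0)
  if (f0_start >= 1) stop("bleach floor F0 >= 1: nothing was bleached", call. = FALSE)
  t_max <- max(t[t > 0])
  # The model is fitted in a bounded reparameterization: plateau P = F0 + A1
  # + A2 (capped at 1.05 -- a normalized curve cannot recover above its
  # pre-bleach level) and weight w = A1 / (A1 + A2). This keeps the
  # extrapolated plateau physical and stays identifiable when the recovery
  # is effectively single-exponential. Time constants are capped at 3x the
  # window so an unresolvable slow term cannot act as a drift absorber.
  tau_hi <- 3 * t_max
  tau1s <- pmin(t_max / 10^seq(2.5, 0, length.out = max(5L, n_starts)), tau_hi)
  starts <- list()
  for (t1 in tau1s) for (m2 in c(10, 100)) {
    starts[[length(starts) + 1L]] <-
      list(f0 = f0_start, p = min(max(y), 1.05), w = 0.7,
           tau1 = t1, tau2 = min(t1 * m2, tau_hi))
  }
  model_fn <- function(par) {
    par[["f0"]] + (par[["p"]] - par[["f0"]]) *
      (par[["w"]] * (1 - exp(-t / par[["tau1"]])) +
         (1 - par[["w"]]) * (1 - exp(-t / par[["tau2"]])))
  }
  best <- NULL; best_ss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = unlist(st), fn = function(par) y - model_fn(par),
        lower = c(f0 = 0, p = 0, w = 0, tau1 = 1e-4, tau2 = 1e-4),
        upper = c(f0 = 1, p = 1.05, w = 1, tau1 = tau_hi, tau2 = tau_hi),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$info %in% 1:4 && is.finite(fit$deviance)) {
      if (fit$deviance < best_ss) { best_ss <- fit$deviance; best <- fit }
    }
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE), class = "frap_fit"))
  }
  cf <- as.list(best$par)
  p <- list(f0 = cf$f0, a1 = cf$w * (cf$p - cf$f0), tau1 = cf$tau1,
            a2 = (1 - cf$w) * (cf$p - cf$f0), tau2 = cf$tau2)
  if (p$tau1 > p$tau2) {  # relabel so tau1 is the fast component
    p[c("a1", "tau1", "a2", "tau2")] <- p[c("a2", "tau2", "a1", "tau1")]
  }
  plateau_gain <- p$a1 + p$a2
  mobile_raw <- plateau_gain / (1 - p$f0)
  mobile <- min(max(mobile_raw, 0), 1)
  # t_half on the fitted curve: F(t) = F0 + plateau_gain / 2
  target <- p$f0 + plateau_gain / 2
  t_half <- tryCatch(
    stats::uniroot(function(tt) {
      .frap_model(tt, p$f0, p$a1, p$tau1, p$a2, p$tau2) - target
    }, lower = 0, upper = 1e4 * max(p$tau2, t_max), tol = 1e-10)$root,
    error = function(e) NA_real_
  )
  structure(list(
    converged = TRUE,
    f0 = p$f0, a1 = p$a1, tau1 = p$tau1, a2 = p$a2, tau2 = p$tau2,
    mobile_fraction = mobile,
    mobile_fraction_raw = mobile_raw,
    immobile_fraction = 1 - mobile,
    plateau_gain = plateau_gain,
    t_half = t_half,
    rss = best_ss,
    n = nrow(post),
    curve = post
  ), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<frap_fit> DID NOT CONVERGE\n"); return(invisible(x))
  }
  cat("<frap_fit> F(t) = F0 + A1(1-exp(-t/tau1)) + A2(1-exp(-t/tau2))\n")
  cat(sprintf("  F0 = %.3f, A1 = %.3f (tau1 = %.3g s), A2 = %.3f (tau2 = %.3g s)\n",
              x$f0, x$a1, x$tau1, x$a2, x$tau2))
  cat(sprintf("  mobile fraction = %.3f (immobile %.3f), t1/2 = %.3g s\n",
              x$mobile_fraction, x$immobile_fraction, x$t_half))
  invisible(x)
}

#' Tidy a FRAP fit
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return One row per model parameter: `term`, `estimate`.
#' @export
tidy.frap_fit <- function(x, ...) {
  if (!x$converged) return(tibble::tibble(term = character(), estimate = double()))
  tibble::tibble(
    term = c("f0", "a1", "tau1", "a2", "tau2"),
    estimate = c(x$f0, x$a1, x$tau1, x$a2, x$tau2)
  )
}

#' One-row summary of a FRAP fit
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the derived mobility quantities.
#' @export
glance.frap_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(converged = FALSE, mobile_fraction = NA_real_,
                          immobile_fraction = NA_real_, t_half = NA_real_,
                          rss = NA_real_, n = NA_integer_))
  }
  tibble::tibble(converged = TRUE,
                 mobile_fraction = x$mobile_fraction,
                 immobile_fraction = x$immobile_fraction,
                 t_half = x$t_half, rss = x$rss, n = x$n)
}

#' Predict the fitted recovery curve
#' @param object A `frap_fit`.
#' @param newdata Optional tibble with a `time_s` column.
#' @param ... Unused.
#' @return Numeric vector of fitted intensities.
#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  stopifnot(object$converged)
  t <- if (is.null(newdata)) object$curve$time_s else newdata$time_s
  .frap_model(t, object$f0, object$a1, object$tau1, object$a2, object$tau2)
}

#' Effective diffusion coefficient from half-time fold change
#'
#' Scales a reference fluorophore's known cytoplasmic diffusion coefficient
#' by the fold slowdown of the recovery half time: diffusion time scales as
#' 1/D, so a species recovering n-fold slower has an n-fold smaller effective
#' D. Given ranges for the measured and reference half times and the
#' reference D, the widest interval implied by the endpoints is returned:
#' `D_low = ref_D_low / fold_max`, `D_high = ref_D_high / fold_min`.
#'
#' @param t_half Measured half time(s), s (length 1 or 2).
#' @param ref_t_half Reference fluorophore half time(s), s.
#' @param ref_D_low,ref_D_high Reference diffusion coefficient range,
#'   um^2/s. Defaults to the cytoplasmic GFP range 25-30 um^2/s.
#' @return A one-row tibble: `d_low`, `d_high`, `fold_min`, `fold_max`.
#' @export
estimate_effective_d <- function(t_half, ref_t_half,
                                 ref_D_low = 25, ref_D_high = 30) {
  if (any(t_half <= 0) || any(ref_t_half <= 0)) {
    stop("half times must be positive", call. = FALSE)
  }
  stopifnot(ref_D_low > 0, ref_D_high >= ref_D_low)
  fold_min <- min(t_half) / max(ref_t_half)
  fold_max <- max(t_half) / min(ref_t_half)
  tibble::tibble(
    d_low = ref_D_low / fold_max,
    d_high = ref_D_high / fold_min,
    fold_min = fold_min, fold_max = fold_max
  )
}

#' Soumpasis closed-form diffusion coefficient (cross-check)
#'
#' The classical closed form for pure 2D diffusion into a circular bleach
#' spot, `D = 0.224 * r^2 / t_half`. Provided as an independent cross-check
#' of [estimate_effective_d()]; the half-time-ratio route is the primary
#' estimator because it cancels unknown geometry against a co-acquired
#' reference.
#'
#' @param t_half Recovery half time, s.
#' @param roi_radius Bleach spot radius, um.
#' @return D in um^2/s.
#' @export
soumpasis_d <- function(t_half, roi_radius) {
  stopifnot(t_half > 0, roi_radius > 0)
  0.224 * roi_radius^2 / t_half
}
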