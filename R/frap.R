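#' Construct a FRAP trace
#'
#' Raw mean intensities of the bleached region of interest, a background
#' region outside any condensate, and an unbleached reference condensate
#' that reports acquisition photobleaching.  The bleach happens at
#' t = 0; frames with negative times are pre-bleach.
#'
#' @param times time stamps in seconds (strictly increasing; bleach at 0).
#' @param roi,background,reference raw intensities per time point (a.u.).
#' @param n_prebleach number of pre-bleach frames; default counts
#'   `times < 0`.
#' @return a `frap_trace` object.
#' @export
frap_trace <- function(times, roi, background, reference,
                       n_prebleach = sum(times < 0)) {
  stopifnot(length(times) == length(roi),
            length(times) == length(background),
            length(times) == length(reference))
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (n_prebleach < 3L)
    stop("need at least 3 pre-bleach frames", call. = FALSE)
  if (length(times) - n_prebleach < 10L)
    stop("need at least 10 post-bleach frames", call. = FALSE)
  out <- list(times = as.numeric(times), roi = as.numeric(roi),
              background = as.numeric(background),
              reference = as.numeric(reference),
              n_prebleach = as.integer(n_prebleach))
  class(out) <- "frap_trace"
  out
}

#' Double-normalize a FRAP trace
#'
#' Background-subtracts the ROI and reference channels, divides the ROI
#' by the reference to cancel acquisition photobleaching, and rescales
#' so the pre-bleach mean is 1:
#' `N(t) = [(ROI - bg) / (ref - bg)] / prebleach mean of the same ratio`.
#' Frames whose reference drops below 50% of its pre-bleach mean are
#' trimmed with a warning (catastrophic reference bleaching).
#'
#' @param trace a [frap_trace].
#' @return list with `times`, `values` (normalized N(t)), `n_prebleach`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  pre <- seq_len(trace$n_prebleach)
  ref_net <- trace$reference - trace$background
  bad <- which(ref_net <= 0)
  if (length(bad))
    stop("reference - background is non-positive at frame ", bad[1],
         call. = FALSE)
  ref_pre <- mean(trace$reference[pre])
  keep <- trace$reference >= 0.5 * ref_pre
  if (!all(keep)) {
    warning(sum(!keep), " frame(s) trimmed: reference below 50% of its ",
            "pre-bleach mean", call. = FALSE)
  }
  ratio <- (trace$roi - trace$background) / ref_net
  norm <- ratio / mean(ratio[pre])
  list(times = trace$times[keep], values = norm[keep],
       n_prebleach = sum(keep[pre]))
}

#' Fit a single-exponential FRAP recovery
#'
#' Fits `N(t) = F0 + (plateau - F0) * (1 - exp(-k t))` to the post-bleach
#' part of a normalized trace by bounded least squares
#' (`F0 in [0, 1]`, `plateau in [F0, 1.2]`, `k > 0`), and derives the
#' half-time `t_half = ln 2 / k`, the mobile fraction
#' `(plateau - F0) / (1 - F0)` and the immobile fraction `1 - mobile`.
#'
#' Initialization is deterministic: `F0` from the first post-bleach
#' value, the plateau from the mean of the final 10% of frames, and `k`
#' from a log-linear regression of `plateau - N(t)`.
#'
#' @param normalized output of [normalize_trace()], or any list with
#'   `times` and `values` where the pre-bleach mean is 1 and the bleach
#'   is at t = 0.
#' @return a `frap_fit`: list with `F0`, `plateau`, `k`, `t_half`,
#'   `mobile_fraction`, `immobile_fraction`, `rms_residual`, `flagged`
#'   (TRUE when k is unidentifiable, e.g. a flat post-bleach trace).
#' @export
fit_recovery <- function(normalized) {
  tt <- normalized$times
  vv <- normalized$values
  post <- tt >= 0
  t_post <- tt[post]
  y <- vv[post]
  if (length(y) < 5L) stop("too few post-bleach points to fit",
                           call. = FALSE)
  F0_init <- min(max(y[1], 0), 1)
  tail_n <- max(3L, ceiling(0.1 * length(y)))
  plateau_init <- mean(utils::tail(y, tail_n))
  plateau_init <- min(max(plateau_init, F0_init + 1e-6), 1.2)
  flat <- stats::sd(y) < 1e-8 || (plateau_init - F0_init) < 1e-6
  if (flat) {
    out <- list(F0 = y[1], plateau = y[1], k = NA_real_, t_half = NA_real_,
                mobile_fraction = 0, immobile_fraction = 1,
                rms_residual = stats::sd(y), flagged = TRUE)
    class(out) <- "frap_fit"
    return(out)
  }
  # log-linear slope of (plateau - N) gives the initial rate
  gap <- plateau_init - y
  ok <- gap > 1e-4 * (plateau_init - F0_init)
  k_init <- if (sum(ok) >= 3) {
    fit0 <- stats::lm.fit(cbind(1, t_post[ok]), log(gap[ok]))
    max(-unname(fit0$coefficients[2]), 1e-4)
  } else 0.1
  lower <- c(F0 = 0, plateau = 1e-8, k = 1e-6)
  upper <- c(F0 = 1, plateau = 1.2, k = 100)
  start <- list(F0 = F0_init, plateau = plateau_init, k = k_init)
  fit_df <- data.frame(t = t_post, y = y)
  nls_fit <- tryCatch(
    stats::nls(y ~ F0 + (plateau - F0) * (1 - exp(-k * t)),
               data = fit_df, start = start, algorithm = "port",
               lower = lower, upper = upper,
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(nls_fit)) {
    p <- stats::coef(nls_fit)
    rss <- sum(stats::resid(nls_fit)^2)
  } else {
    # fallback for degenerate residual surfaces (e.g. zero noise)
    obj <- function(p) {
      sum((y - (p[1] + (p[2] - p[1]) * (1 - exp(-p[3] * t_post))))^2)
    }
    ofit <- stats::optim(unlist(start), obj, method = "L-BFGS-B",
                         lower = lower, upper = upper,
                         control = list(maxit = 500, factr = 1e4))
    if (!is.finite(ofit$value))
      stop("recovery fit failed to converge (init F0=",
           signif(F0_init, 3), ", plateau=", signif(plateau_init, 3),
           ", k=", signif(k_init, 3), "; residual SS=",
           signif(ofit$value, 4), ")", call. = FALSE)
    p <- ofit$par
    rss <- ofit$value
  }
  F0 <- unname(p[1]); plateau <- max(unname(p[2]), F0); k <- unname(p[3])
  mobile <- if (F0 < 1) (plateau - F0) / (1 - F0) else 0
  mobile <- min(max(mobile, 0), 1)
  out <- list(F0 = F0, plateau = plateau, k = k, t_half = log(2) / k,
              mobile_fraction = mobile, immobile_fraction = 1 - mobile,
              rms_residual = sqrt(rss / length(y)), flagged = FALSE)
  class(out) <- "frap_fit"
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit>\n")
  if (x$flagged) {
    cat("  flat post-bleach trace: k unidentifiable, mobile fraction 0\n")
  } else {
    cat(sprintf("  k = %.4f /s, t_half = %.2f s\n", x$k, x$t_half))
    cat(sprintf("  F0 = %.3f, plateau = %.3f\n", x$F0, x$plateau))
    cat(sprintf("  mobile %.1f%%, immobile %.1f%% (RMS %.4f)\n",
                100 * x$mobile_fraction, 100 * x$immobile_fraction,
                x$rms_residual))
  }
  invisible(x)
}

#' Analyze a table of FRAP traces
#'
#' @param df long-format data frame with columns `trace_id`, `t_s`,
#'   `roi`, `background`, `reference` (single traces may omit
#'   `trace_id`).
#' @param n_prebleach pre-bleach frame count passed to [frap_trace()];
#'   default counts negative times per trace.
#' @return data frame with one fitted row per trace.
#' @export
fit_frap_table <- function(df, n_prebleach = NULL) {
  if (!"trace_id" %in% names(df)) df$trace_id <- 1L
  ids <- unique(df$trace_id)
  do.call(rbind, lapply(ids, function(id) {
    d <- df[df$trace_id == id, , drop = FALSE]
    np <- if (is.null(n_prebleach)) sum(d$t_s < 0) else n_prebleach
    tr <- frap_trace(d$t_s, d$roi, d$background, d$reference, np)
    ft <- fit_recovery(normalize_trace(tr))
    data.frame(trace_id = id, F0 = ft$F0, plateau = ft$plateau, k = ft$k,
               t_half = ft$t_half, mobile_fraction = ft$mobile_fraction,
               immobile_fraction = ft$immobile_fraction,
               rms_residual = ft$rms_residual, flagged = ft$flagged)
  }))
}
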