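#' Relative expression by the 2^-ddCt method
#'
#' `dCt = target Ct - mean(reference Cts)`, `ddCt = dCt - calibrator
#' dCt`, relative expression `2^-ddCt`.  Several reference genes (e.g.
#' 18S and 5S rRNA) are aggregated by the arithmetic mean of their Ct
#' values, i.e. the geometric mean of their linear quantities.
#'
#' @param target_ct target-gene Ct.
#' @param reference_cts numeric vector of reference-gene Cts (>= 1).
#' @param calibrator_delta_ct the calibrator sample's dCt.
#' @return positive relative expression.
#' @export
ddct <- function(target_ct, reference_cts, calibrator_delta_ct) {
  if (!length(reference_cts)) stop("at least one reference Ct required")
  cts <- c(target_ct, reference_cts, calibrator_delta_ct)
  if (any(!is.finite(cts))) stop("non-finite Ct value")
  if (target_ct <= 0 || target_ct >= 50 ||
      any(reference_cts <= 0 | reference_cts >= 50))
    stop("Ct values must lie in (0, 50)")
  dct <- target_ct - mean(reference_cts)
  2^-(dct - calibrator_delta_ct)
}

#' Construct a decay time course
#'
#' Relative abundance over hours post transcription block (actinomycin
#' D added at t = 0).  Abundance is renormalised so the t = 0 value is
#' exactly 1.
#'
#' @param timepoints strictly increasing hours, first must be 0.
#' @param abundance positive relative abundances, parallel to
#'   `timepoints`.
#' @param gene_id,condition labels.
#' @return a `decay_timecourse` data.frame.
#' @export
decay_timecourse <- function(timepoints, abundance, gene_id = NA_character_,
                             condition = NA_character_) {
  if (length(timepoints) != length(abundance))
    stop("timepoints and abundance lengths differ")
  if (timepoints[1L] != 0) stop("first timepoint must be 0")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (any(abundance <= 0)) stop("abundance must be positive")
  structure(data.frame(gene_id = gene_id, condition = condition,
                       time = timepoints,
                       abundance = abundance / abundance[1L],
                       stringsAsFactors = FALSE),
            class = c("decay_timecourse", "data.frame"))
}

#' Fit first-order decay and estimate the half-life
#'
#' Fits `N(t) = N0 * exp(-k t)` by least squares on the log scale
#' (closed form via `lm(log(N) ~ t)`), giving the decay constant `k`
#' (per hour), `t_half = ln(2) / k` and the R-squared of the log-linear
#' fit.  A non-decaying fit (`k <= 0`) reports an infinite half-life
#' and is flagged.  `method = "nls"` refits on the linear scale by
#' nonlinear least squares (Gauss-Newton, initialised from the
#' log-linear estimate) for users preferring untransformed residuals.
#'
#' @param tc a [decay_timecourse()] (or data.frame with `time` and
#'   `abundance`), >= 3 timepoints.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return list of class `half_life_estimate`: `k`, `t_half`,
#'   `r_squared`, `n0`, `decaying` (logical flag).
#' @export
fit_decay <- function(tc, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  if (nrow(tc) < 3L) stop("need at least 3 timepoints")
  if (any(tc$abundance <= 0)) stop("abundance must be positive")
  fit <- stats::lm(log(abundance) ~ time, data = tc)
  k <- -unname(stats::coef(fit)[2L])
  n0 <- exp(unname(stats::coef(fit)[1L]))
  y <- log(tc$abundance)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::resid(fit)^2) / sst
  if (method == "nls") {
    nfit <- stats::nls(abundance ~ n0 * exp(-k * time), data = tc,
                       start = list(n0 = n0, k = max(k, 1e-6)),
                       control = stats::nls.control(maxiter = 200,
                                                    scaleOffset = 1))
    k <- unname(stats::coef(nfit)["k"])
    n0 <- unname(stats::coef(nfit)["n0"])
    res <- stats::resid(nfit)
    r2 <- 1 - sum(res^2) / sum((tc$abundance - mean(tc$abundance))^2)
  }
  decaying <- k > 0
  structure(list(k = k,
                 t_half = if (decaying) log(2) / k else Inf,
                 r_squared = max(0, min(1, r2)),
                 n0 = n0,
                 decaying = decaying),
            class = "half_life_estimate")
}

#' @export
print.half_life_estimate <- function(x, ...) {
  cat(sprintf("half-life estimate: k = %.4g /h, T1/2 = %.4g h, R^2 = %.4f%s\n",
              x$k, x$t_half, x$r_squared,
              if (!x$decaying) " [non-decaying]" else ""))
  invisible(x)
}

#' Compare two half-life estimates
#'
#' Half-life ratio and stability ordering; an infinite half-life (no
#' decay) ranks as most stable.
#'
#' @param est_a,est_b [fit_decay()] results.
#' @return list: `ratio` (`t_half_a / t_half_b`), `more_stable`
#'   (`"a"`, `"b"` or `"equal"`).
#' @export
compare_halflives <- function(est_a, est_b) {
  ta <- est_a$t_half; tb <- est_b$t_half
  ratio <- if (is.infinite(ta) && is.infinite(tb)) 1 else ta / tb
  list(ratio = ratio,
       more_stable = if (ta > tb) "a" else if (tb > ta) "b" else "equal")
}
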