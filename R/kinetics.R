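#' Double-normalize a FRAP trace
#'
#' Background-subtracts both the bleach-spot ROI and the whole-compartment
#' reference, then forms the double normalization
#' `(roi(t) / roi_pre) / (whole(t) / whole_pre)` with pre-bleach means as
#' references. The whole-compartment ratio cancels acquisition
#' photobleaching that affects ROI and reference alike, and the pre-bleach
#' normalized mean is 1 by construction. A full-scale variant (ignoring the
#' reference channel) is available behind `method = "full_scale"`.
#'
#' @param trace tibble with `time_s`, `roi_intensity`, `whole_intensity`,
#'   `background`; the bleach frame is taken from the `bleach_frame`
#'   attribute (as produced by [make_frap_trace()]) or passed explicitly.
#' @param bleach_frame row index of the first post-bleach sample.
#' @param method `"double"` (default) or `"full_scale"`.
#' @return tibble `time_s`, `t_post_s` (0 at the first post-bleach sample,
#'   negative before), `normalized`, `phase`; attribute `bleach_frame`.
#' @export
normalize_frap <- function(trace, bleach_frame = attr(trace, "bleach_frame"),
                           method = c("double", "full_scale")) {
  method <- match.arg(method)
  needed <- c("time_s", "roi_intensity", "whole_intensity", "background")
  if (!all(needed %in% names(trace))) {
    abort("`trace` needs columns time_s, roi_intensity, whole_intensity, background.")
  }
  if (is.null(bleach_frame)) abort("`bleach_frame` is required.")
  bleach_frame <- check_count(bleach_frame, "bleach_frame", min = 2L)
  if (bleach_frame < 4L) abort("need at least 3 pre-bleach frames.")
  roi <- trace$roi_intensity - trace$background
  whole <- trace$whole_intensity - trace$background
  if (any(whole <= 0)) abort("whole-compartment intensity <= background; trace unusable.")
  pre <- seq_len(bleach_frame - 1L)
  roi_n <- roi / mean(roi[pre])
  norm <- if (method == "double") {
    roi_n / (whole / mean(whole[pre]))
  } else {
    roi_n
  }
  out <- tibble(
    time_s = trace$time_s,
    t_post_s = trace$time_s - trace$time_s[bleach_frame],
    normalized = norm,
    phase = ifelse(seq_len(nrow(trace)) < bleach_frame, "pre", "post")
  )
  structure(out, bleach_frame = bleach_frame)
}

#' Fit an exponential recovery model to a normalized FRAP curve
#'
#' Least-squares fit of the post-bleach samples to
#' `I(t) = I0 + A * (1 - exp(-k * t))` (single exponential; `model =
#' "double"` adds a second exponential term). The half recovery time is read
#' from the fitted curve — the time at which the recovery reaches half of
#' `plateau - I0` — which for the single-exponential model is
#' `t_half = log(2) / k`. The mobile fraction is
#' `(plateau - I0) / (1 - I0)`, taking the pre-bleach level as 1.
#'
#' @param curve output of [normalize_frap()] (needs `t_post_s`,
#'   `normalized`, `phase`), with at least 10 post-bleach samples.
#' @param model `"single"` or `"double"` exponential.
#' @return a `frap_fit` list: `k` (1/s), `t_half` (s), `mobile_fraction`,
#'   `plateau`, `I0`, `model`, `converged`; for the double model, `k2` and
#'   `A2`. A recovery amplitude indistinguishable from zero reports
#'   `t_half = NA`.
#' @export
fit_frap <- function(curve, model = c("single", "double")) {
  model <- match.arg(model)
  post <- filter(as_tibble(curve), .data$phase == "post")
  if (nrow(post) < 10) abort("need >= 10 post-bleach samples.")
  t <- post$t_post_s; yv <- post$normalized
  I0 <- yv[1]
  A0 <- max(mean(tail(yv, max(3, length(yv) %/% 10))) - I0, 1e-3)
  k0 <- log(2) / max(t[which.min(abs(yv - (I0 + A0 / 2)))], t[2])
  model_fun <- if (model == "single") {
    function(p, tt) p[1] + p[2] * (1 - exp(-p[3] * tt))
  } else {
    function(p, tt) p[1] + p[2] * (1 - exp(-p[3] * tt)) + p[4] * (1 - exp(-p[5] * tt))
  }
  p0 <- if (model == "single") c(I0, A0, k0) else c(I0, A0 * 0.7, k0, A0 * 0.3, k0 / 10)
  fit <- tryCatch(
    minpack.lm::nls.lm(p0, fn = function(p) model_fun(p, t) - yv,
                       control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(structure(list(k = NA_real_, t_half = NA_real_,
                          mobile_fraction = NA_real_, plateau = NA_real_,
                          I0 = I0, model = model, converged = FALSE),
                     class = "frap_fit"))
  }
  p <- fit$par
  plateau <- if (model == "single") p[1] + p[2] else p[1] + p[2] + p[4]
  amp <- plateau - p[1]
  # t_half from the fitted curve: time to reach I0 + amp/2
  t_half <- if (amp <= 1e-4) {
    NA_real_
  } else if (model == "single") {
    log(2) / p[3]
  } else {
    target <- p[1] + amp / 2
    tryCatch(
      stats::uniroot(function(tt) model_fun(p, tt) - target,
                     c(1e-9, max(t) * 10), extendInt = "upX")$root,
      error = function(e) NA_real_
    )
  }
  mobile <- if (abs(1 - p[1]) < 1e-12) NA_real_ else amp / (1 - p[1])
  structure(
    list(k = p[3], t_half = t_half,
         mobile_fraction = max(min(mobile, 1), 0),
         plateau = plateau, I0 = p[1], model = model, converged = TRUE,
         k2 = if (model == "double") p[5] else NA_real_,
         A2 = if (model == "double") p[4] else NA_real_),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> %s-exponential | k = %.4g /s | t_half = %.4g s | mobile fraction %.3g\n",
              x$model, x$k, x$t_half, x$mobile_fraction))
  invisible(x)
}

#' Fit a one-to-one binding model to SPR sensorgrams
#'
#' Global least squares across one or more concentrations with shared
#' `k_on`, `k_off` and `R_max` (per-curve fits are available with
#' `shared = FALSE` for diagnostics). The model is the closed-form
#' one-to-one Langmuir kinetics of [make_sensorgram()]: exponential approach
#' to `R_eq = R_max * C / (C + K_D)` during association and single-
#' exponential decay during dissociation. `K_D = k_off / k_on` by
#' definition. A single concentration with no dissociation phase leaves
#' `k_on` and `k_off` unidentifiable and is rejected.
#'
#' @param sensorgrams one tibble (or list of tibbles) as produced by
#'   [make_sensorgram()]: columns `time_s`, `response`, `phase`,
#'   `concentration_M`.
#' @param shared fit one global parameter set (default) or one per curve.
#' @return a `binding_fit` list: `k_on`, `k_off`, `K_D`, `R_max`,
#'   `rmse`, `n_curves`, `se` (approximate standard errors), or a list of
#'   per-curve fits when `shared = FALSE`.
#' @export
fit_binding <- function(sensorgrams, shared = TRUE) {
  if (is.data.frame(sensorgrams)) {
    sensorgrams <- split(sensorgrams, sensorgrams$concentration_M)
  }
  sensorgrams <- unname(sensorgrams)
  if (!length(sensorgrams)) abort("no sensorgrams supplied.")
  for (sg in sensorgrams) {
    if (!all(c("time_s", "response", "phase", "concentration_M") %in% names(sg))) {
      abort("each sensorgram needs time_s, response, phase, concentration_M.")
    }
  }
  if (!shared) {
    return(map(sensorgrams, function(sg) fit_binding(list(sg), shared = TRUE)))
  }
  has_dissoc <- any(map_dbl(sensorgrams, ~ sum(.x$phase == "dissociation")) > 2)
  if (length(sensorgrams) == 1 && !has_dissoc) {
    abort("one concentration without a dissociation phase: k_on and k_off are unidentifiable.")
  }
  t_assoc <- map_dbl(sensorgrams, function(sg) {
    a <- sg$time_s[sg$phase == "association"]
    if (length(a)) max(a) else 0
  })
  R_guess <- max(map_dbl(sensorgrams, ~ max(.x$response)))
  # start values: k_off from the tail decay, mid-range k_on
  p0 <- c(log_kon = log(1e5), log_koff = log(1e-3), R_max = R_guess * 1.5)
  resid_fun <- function(p) {
    kon <- exp(p[1]); koff <- exp(p[2]); Rm <- p[3]
    unlist(map2(sensorgrams, t_assoc, function(sg, ta) {
      sensorgram_model(sg$time_s, kon, koff, Rm, sg$concentration_M[1], ta) - sg$response
    }))
  }
  fit <- minpack.lm::nls.lm(p0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  kon <- exp(fit$par[1]); koff <- exp(fit$par[2]); Rm <- fit$par[3]
  # delta-method standard errors from the Jacobian at the optimum
  se <- tryCatch({
    J <- fit$hessian
    cv <- solve(J) * sum(fit$fvec^2) / max(length(fit$fvec) - 3, 1)
    s <- sqrt(pmax(diag(cv), 0))
    c(k_on = kon * s[1], k_off = koff * s[2], R_max = s[3])
  }, error = function(e) c(k_on = NA_real_, k_off = NA_real_, R_max = NA_real_))
  structure(
    list(k_on = unname(kon), k_off = unname(koff), K_D = unname(koff / kon),
         R_max = unname(Rm), rmse = sqrt(mean(fit$fvec^2)),
         n_curves = length(sensorgrams), se = se,
         converged = fit$info %in% 1:4),
    class = "binding_fit"
  )
}

#' Estimate the dissociation rate from a dissociation phase alone
#'
#' The dissociation phase of a one-to-one binding model is a single
#' exponential, so `log(R)` is linear in time with slope `-k_off`. This is
#' the standard per-phase diagnostic (and the only rate identifiable
#' without an association phase).
#'
#' @param sensorgram tibble with `time_s`, `response`, `phase`.
#' @return `k_off` estimate, 1/s.
#' @export
fit_dissociation <- function(sensorgram) {
  d <- filter(sensorgram, .data$phase == "dissociation", .data$response > 0)
  if (nrow(d) < 3) abort("need >= 3 positive dissociation-phase samples.")
  -unname(coef(lm(log(d$response) ~ d$time_s))[2])
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "<binding_fit> k_on = %.4g /(M s) | k_off = %.4g /s | K_D = %.4g nM | R_max = %.4g (%d curve(s))\n",
    x$k_on, x$k_off, x$K_D * 1e9, x$R_max, x$n_curves))
  invisible(x)
}
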