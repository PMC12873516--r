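#' Kinetic parameter set for a dynamic stomatal conductance model
#'
#' Bundles the parameters of one of the four dynamic response models of
#' stomatal conductance (gs) to a step change in light intensity:
#'
#' * `"exponential"`: `gs(t) = g_f + (g_i - g_f) * exp(-t / tau)`.
#'   `tau` (s) is the time to complete 63.2% (1 - 1/e) of the change.
#' * `"sigmoidal"`: the Gompertz form
#'   `gs(t) = g_i + (g_f - g_i) * exp(-exp((lam - t) / tau + 1))`,
#'   where `lam` (s) is a lag constant; with `lam = 0` the response at
#'   `t = tau` has completed 37% (1/e) of the change.
#' * `"cdweibull"`: the two-parameter cumulative-distribution Weibull
#'   (stretched exponential)
#'   `gs(t) = g_f + (g_i - g_f) * exp(-(t / tau)^lam)`,
#'   where the dimensionless shape `lam` moves the curve between exponential
#'   (`lam = 1`, exact collapse) and sigmoidal (`lam > 1`) shapes while
#'   `tau` remains the 63.2% completion time for every `lam`.
#' * `"t63"`: the model-free empirical metric; it carries no closed-form
#'   parameters and is computed by [t63_empirical()].
#'
#' `g_i` and `g_f` are the initial and final steady-state conductances
#' (mol m-2 s-1); `dgs = g_f - g_i` is the response magnitude. Direction
#' (opening vs closing) is metadata carried by callers, not encoded in signs.
#'
#' @param model one of `"exponential"`, `"sigmoidal"`, `"cdweibull"`.
#' @param g_i,g_f initial and final steady-state conductance (mol m-2 s-1),
#'   both >= 0.
#' @param tau time constant (s), > 0.
#' @param lam lag constant (s, >= 0) for the sigmoidal model; dimensionless
#'   shape (> 0) for the CDWeibull model; must be absent (`NULL`) for the
#'   exponential model.
#' @return an object of class `"kinetic_params"`.
#' @seealso [predict_gs()], [slmax()], [t63()]
#' @export
#' @examples
#' p <- kinetic_params("cdweibull", g_i = 0.1, g_f = 0.3, tau = 600, lam = 2)
#' predict_gs(p, c(0, 300, 600))
#' slmax(p)
#' t63(p)
kinetic_params <- function(model = c("exponential", "sigmoidal", "cdweibull"),
                           g_i, g_f, tau, lam = NULL) {
  model <- match.arg(model)
  for (v in list(g_i = g_i, g_f = g_f, tau = tau)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("g_i, g_f and tau must be finite scalars", call. = FALSE)
    }
  }
  if (g_i < 0 || g_f < 0) stop("conductances must be non-negative", call. = FALSE)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (model == "exponential") {
    if (!is.null(lam)) stop("lam is not a parameter of the exponential model", call. = FALSE)
  } else {
    if (is.null(lam) || !is.numeric(lam) || length(lam) != 1L || !is.finite(lam)) {
      stop("lam must be a finite scalar for this model", call. = FALSE)
    }
    if (model == "cdweibull" && lam <= 0) stop("CDWeibull shape lam must be > 0", call. = FALSE)
    if (model == "sigmoidal" && lam < 0) stop("sigmoidal lag lam must be >= 0", call. = FALSE)
  }
  structure(
    list(model = model, g_i = g_i, g_f = g_f, tau = tau, lam = lam),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params: %s> g_i=%.4g g_f=%.4g tau=%.4g s%s\n",
    x$model, x$g_i, x$g_f, x$tau,
    if (is.null(x$lam)) "" else sprintf(" lam=%.4g", x$lam)
  ))
  invisible(x)
}

#' Predict stomatal conductance at time t
#'
#' Evaluates the response model of a [kinetic_params()] object at times `t`
#' (seconds since the light switch). All three closed-form models are
#' monotone between `g_i` and `g_f`.
#'
#' @param p a [kinetic_params()] object.
#' @param t numeric vector of times (s), `>= 0`.
#' @return conductance values (mol m-2 s-1), same length as `t`.
#' @export
predict_gs <- function(p, t) {
  stopifnot(inherits(p, "kinetic_params"))
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t))) {
    stop("t must be finite numeric", call. = FALSE)
  }
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  switch(p$model,
    exponential = p$g_f + (p$g_i - p$g_f) * exp(-t / p$tau),
    sigmoidal   = p$g_i + (p$g_f - p$g_i) * exp(-exp((p$lam - t) / p$tau + 1)),
    cdweibull   = p$g_f + (p$g_i - p$g_f) * exp(-(t / p$tau)^p$lam)
  )
}

#' Maximum slope (Slmax) of a response model
#'
#' Returns the maximum instantaneous rate of change of gs (mol m-2 s-2)
#' during the response, as a magnitude (direction is carried separately by
#' callers). Closed forms:
#'
#' * exponential: `|dgs| / tau`, attained at `t = 0`;
#' * sigmoidal: `|dgs| / (e * tau)`, attained at `t = lam + tau`;
#' * CDWeibull, `lam > 1`:
#'   `|dgs| * (lam / tau) * q^q * exp(-q)` with `q = (lam - 1) / lam`,
#'   attained at `t* = tau * q^(1/lam)`;
#' * CDWeibull, `lam = 1`: `|dgs| / tau` (exponential collapse).
#'
#' For CDWeibull shapes `lam < 1` the slope is unbounded as `t -> 0+`; the
#' slope evaluated at `t = eps` is returned with attribute
#' `boundary = TRUE`.
#'
#' @param p a [kinetic_params()] object (closed-form models only).
#' @param eps minimum evaluation time (s) used when `lam < 1` (default 1 s).
#' @return the maximum slope (mol m-2 s-2); attribute `t_at` gives the time
#'   at which it is attained, attribute `boundary` flags the `lam < 1` case.
#' @export
slmax <- function(p, eps = 1) {
  stopifnot(inherits(p, "kinetic_params"))
  dg <- abs(p$g_f - p$g_i)
  out <- switch(p$model,
    exponential = structure(dg / p$tau, t_at = 0),
    sigmoidal   = structure(dg / (exp(1) * p$tau), t_at = p$lam + p$tau),
    cdweibull   = {
      l <- p$lam
      if (l == 1) {
        structure(dg / p$tau, t_at = 0)
      } else if (l > 1) {
        q <- (l - 1) / l
        structure(dg * (l / p$tau) * q^q * exp(-q), t_at = p$tau * q^(1 / l))
      } else {
        # supremum infinite; report slope at the configured minimum time
        u <- (eps / p$tau)^l
        structure(dg * (l / eps) * u * exp(-u), t_at = eps, boundary = TRUE)
      }
    }
  )
  out
}

#' Time to 63% completion (t63) of a response model
#'
#' Time at which `|gs(t) - g_i| = (1 - 1/e) * |dgs|`. Closed forms:
#' exponential `tau`; CDWeibull `tau` for every shape `lam`; sigmoidal
#' `lam + tau * (1 - log(-log(1 - exp(-1))))` (approximately
#' `lam + 1.7793 * tau`).
#'
#' @param p a [kinetic_params()] object (closed-form models only).
#' @return time (s).
#' @export
t63 <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (p$g_f == p$g_i) stop("t63 undefined for dgs = 0", call. = FALSE)
  switch(p$model,
    exponential = p$tau,
    cdweibull   = p$tau,
    sigmoidal   = p$lam + p$tau * (1 - log(-log(1 - exp(-1))))
  )
}

#' Empirical t63 from a curated time course
#'
#' Model-free estimate of the 63.2% completion time. A cubic smoothing
#' spline is fitted to gs(t); the initial and final steady values are read
#' off the spline over plateau windows at the segment ends, and the first
#' crossing time of `g_i + (1 - 1/e) * dgs` is located on a dense spline
#' grid.
#'
#' The smoothing factor is passed to [stats::smooth.spline()] as `spar`;
#' smoothing-parameter semantics are dialect-sensitive across spline
#' implementations, so the factor is exposed (default 0.005, close to an
#' interpolating fit).
#'
#' @param time,gs numeric vectors: time (s, strictly increasing) and
#'   conductance. A two-column data frame may be passed as `time`. The
#'   series may include a pre-switch plateau (points before `switch_time`).
#' @param switch_time time of the light switch (default: the first sample).
#'   `g_i` is read from the spline over the pre-switch window (or at the
#'   switch itself when no pre-switch data exist) and the returned crossing
#'   time is measured from `switch_time`.
#' @param smoothing spline smoothing factor (see Details).
#' @param plateau_window length (s) of the endpoint plateau windows from
#'   which `g_i` and `g_f` are averaged (default 300 s = 5 min).
#' @param grid_n number of points of the evaluation grid.
#' @return time (s) since `switch_time` of the first crossing. Attribute
#'   `multi_crossing` is set to `TRUE` when the smoothed curve crosses the
#'   level more than once (the first crossing is returned). Errors with
#'   class `"stomkin_no_response"` when `dgs` is indistinguishable from 0
#'   and `"stomkin_not_reached"` when the level is never crossed.
#' @export
t63_empirical <- function(time, gs = NULL, switch_time = NULL,
                          smoothing = 0.005, plateau_window = 300,
                          grid_n = 4000L) {
  if (is.data.frame(time)) {
    gs <- time$gs
    time <- time$time
  }
  stopifnot(is.numeric(time), is.numeric(gs), length(time) == length(gs))
  if (length(time) < 8L) stop("too few points for spline fit", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (is.null(switch_time)) switch_time <- time[1L]

  sp <- stats::smooth.spline(time, gs, spar = smoothing)
  tt <- seq(min(time), max(time), length.out = grid_n)
  yy <- stats::predict(sp, tt)$y

  pre <- tt <= switch_time & tt >= switch_time - plateau_window
  g_i <- if (any(pre)) mean(yy[pre]) else yy[1L]
  g_f <- mean(yy[tt >= max(time) - plateau_window])
  dg <- g_f - g_i
  if (abs(dg) < 1e-12) {
    stop(structure(
      class = c("stomkin_no_response", "error", "condition"),
      list(message = "no identifiable response (dgs ~ 0)", call = NULL)
    ))
  }

  level <- g_i + (1 - exp(-1)) * dg
  post <- tt >= switch_time
  tp <- tt[post]
  # completion measured from g_i in the direction of dg
  comp <- (yy[post] - g_i) / dg
  crossed <- comp >= (1 - exp(-1))
  if (!any(crossed)) {
    stop(structure(
      class = c("stomkin_not_reached", "error", "condition"),
      list(message = "63% level not reached within segment", call = NULL)
    ))
  }
  idx <- which(crossed)[1L]
  if (idx == 1L) {
    t_cross <- tp[1L]
  } else {
    # linear interpolation between grid neighbours
    t0 <- tp[idx - 1L]; t1 <- tp[idx]
    c0 <- comp[idx - 1L]; c1 <- comp[idx]
    t_cross <- t0 + (t1 - t0) * ((1 - exp(-1)) - c0) / (c1 - c0)
  }
  n_cross <- sum(diff(crossed) != 0)
  structure(t_cross - switch_time, multi_crossing = n_cross > 1,
            g_i = g_i, g_f = g_f, level = level)
}
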