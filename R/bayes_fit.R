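#' Configuration for hierarchical set fitting
#'
#' A "set" is at least three same-direction gs response curves from the same
#' species and source, fitted jointly with a shared time constant `tau` (and
#' shape/lag `lam` where the model has one) and per-curve endpoints
#' `g_i`, `g_f`, under a homoscedastic Gaussian residual model.
#'
#' Priors default to weakly-informative choices covering the observed 1-100
#' min range of stomatal time constants: `tau ~ LogNormal(log 600, 1)` s,
#' CDWeibull shape `lam ~ LogNormal(0, 0.5)`, sigmoidal lag
#' `lam ~ HalfNormal(300)` s, endpoints `~ Normal(data plateau medians,
#' 0.05)` truncated at 0, residual `sigma ~ HalfNormal(0.01)`.
#'
#' If the first sampling attempt fails the diagnostic gate (all-parameter
#' ESS above `ess_threshold` and split R-hat below `rhat_max`), sampling is
#' escalated: warm-up raised from `n_warmup` to `n_warmup_escalated` and the
#' number of sampling iterations doubled, up to `max_attempts` attempts.
#' Sets still failing are returned with `converged = FALSE` and should not
#' be used downstream.
#'
#' @param n_chains number of MCMC chains (default 4).
#' @param n_warmup warm-up iterations per chain (default 2000).
#' @param n_warmup_escalated warm-up used on escalation retries (default 3000).
#' @param n_sampling sampling iterations per chain (default 1000).
#' @param ess_threshold minimum effective sample size (default 100,
#'   sufficient to describe 95% probability intervals).
#' @param rhat_max maximum split R-hat (default 1.05).
#' @param max_attempts sampling attempts including escalations (default 3).
#' @param target_accept random-walk proposal acceptance target (default
#'   0.234, the random-walk optimum).
#' @param priors named list overriding prior hyperparameters: `tau_meanlog`,
#'   `tau_sdlog`, `lam_meanlog`, `lam_sdlog`, `lam_halfnormal_sd`,
#'   `endpoint_sd`, `sigma_halfnormal_sd`.
#' @param endpoints `"joint"` (default) samples per-curve `g_i`/`g_f`;
#'   `"fixed"` pins them at the data plateau medians.
#' @param seed integer seed; every fit derives its chain seeds from it.
#' @return a list of class `"fit_config"`.
#' @export
fit_config <- function(n_chains = 4L, n_warmup = 2000L,
                       n_warmup_escalated = 3000L, n_sampling = 1000L,
                       ess_threshold = 100, rhat_max = 1.05,
                       max_attempts = 3L, target_accept = 0.234,
                       priors = list(), endpoints = c("joint", "fixed"),
                       seed = 1L) {
  stopifnot(n_chains >= 1, n_warmup > 0, n_sampling > 0,
            target_accept > 0, target_accept < 1)
  pr <- utils::modifyList(list(
    tau_meanlog = log(600), tau_sdlog = 1,
    lam_meanlog = 0, lam_sdlog = 0.5,
    lam_halfnormal_sd = 300,
    endpoint_sd = 0.05,
    sigma_halfnormal_sd = 0.01
  ), priors)
  structure(list(
    n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
    n_warmup_escalated = as.integer(n_warmup_escalated),
    n_sampling = as.integer(n_sampling),
    ess_threshold = ess_threshold, rhat_max = rhat_max,
    max_attempts = as.integer(max_attempts),
    target_accept = target_accept, priors = pr,
    endpoints = match.arg(endpoints), seed = as.integer(seed)
  ), class = "fit_config")
}

# Coerce fitting input to a list of data frames (time since switch, gs).
.fit_points <- function(segments) {
  lapply(segments, function(s) {
    if (inherits(s, "response_segment")) segment_points(s)
    else if (is.data.frame(s) && all(c("time", "gs") %in% names(s))) s[c("time", "gs")]
    else stop("segments must be response_segment objects or (time, gs) data frames",
              call. = FALSE)
  })
}

# Crude data-driven start values for one curve set.
.fit_init <- function(pts) {
  gi <- vapply(pts, function(p) stats::median(utils::head(p$gs, 3L)), 0.0)
  gf <- vapply(pts, function(p) stats::median(utils::tail(p$gs, 5L)), 0.0)
  tau0 <- stats::median(vapply(seq_along(pts), function(k) {
    p <- pts[[k]]
    comp <- (p$gs - gi[k]) / (gf[k] - gi[k] + 1e-12)
    hit <- which(comp >= 1 - exp(-1))
    if (length(hit)) max(p$time[hit[1L]], 1) else max(p$time) / 3
  }, 0.0))
  list(gi = pmax(gi, 1e-4), gf = pmax(gf, 1e-4), tau = max(tau0, 5), sigma = 0.005)
}

#' Fit a set of response segments with a shared time constant
#'
#' Hierarchical Bayesian fit of `model` to >= 3 same-direction curves:
#' shared `tau` (and `lam` for sigmoidal/CDWeibull), per-curve `g_i`/`g_f`,
#' Gaussian residual sd `sigma` shared across the set. Sampling uses
#' adaptive random-walk Metropolis chains satisfying the ESS/R-hat gate of
#' [fit_config()]; failed gates trigger the escalation schedule.
#'
#' @param segments list of [response_segment] objects (or data frames with
#'   `time` in seconds since the switch and `gs`), all with the same
#'   direction of response.
#' @param model `"exponential"`, `"sigmoidal"` or `"cdweibull"`.
#' @param cfg a [fit_config()].
#' @param set_id identifier recorded on the fit.
#' @return object of class `"kinetic_fit"`: posterior `draws` (natural
#'   scale), `summary` table (mean, sd, quantiles, ESS, R-hat per
#'   parameter), `rmse`, `converged`, `n_divergent` (0 for this backend),
#'   `direction`, `seed`, and the fitted points.
#' @export
fit_set <- function(segments, model = c("cdweibull", "exponential", "sigmoidal"),
                    cfg = fit_config(), set_id = "set") {
  model <- match.arg(model)
  if (length(segments) < 3L) {
    stop(structure(class = c("stomkin_insufficient_set", "error", "condition"),
                   list(message = "a set requires at least 3 curves", call = NULL)))
  }
  dirs <- vapply(segments, function(s) {
    if (inherits(s, "response_segment")) s$step$direction else {
      p <- s
      if (stats::median(utils::tail(p$gs, 5L)) >= stats::median(utils::head(p$gs, 3L)))
        "INCREASE" else "DECREASE"
    }
  }, "")
  if (length(unique(dirs)) > 1L) {
    stop(structure(class = c("stomkin_invalid_set", "error", "condition"),
                   list(message = "mixed response directions in set", call = NULL)))
  }
  pts <- .fit_points(segments)
  K <- length(pts)
  init <- .fit_init(pts)
  has_lam <- model != "exponential"
  joint <- cfg$endpoints == "joint"
  pr <- cfg$priors

  t_all <- unlist(lapply(pts, `[[`, "time"))
  y_all <- unlist(lapply(pts, `[[`, "gs"))
  idx <- rep(seq_len(K), vapply(pts, nrow, 0L))
  lt_all <- log(pmax(t_all, 1e-12))

  # theta layout: log_tau [, log_lam] [, g_i(K), g_f(K)] , log_sigma
  nm <- c("tau", if (has_lam) "lam",
          if (joint) c(paste0("g_i[", seq_len(K), "]"),
                       paste0("g_f[", seq_len(K), "]")),
          "sigma")
  unpack <- function(th) {
    o <- 1L
    tau <- exp(th[o]); o <- o + 1L
    lam <- if (has_lam) { v <- exp(th[o]); o <- o + 1L; v } else NULL
    if (joint) {
      gi <- th[o:(o + K - 1L)]; o <- o + K
      gf <- th[o:(o + K - 1L)]; o <- o + K
    } else {
      gi <- init$gi; gf <- init$gf
    }
    sigma <- exp(th[o])
    list(tau = tau, lam = lam, gi = gi, gf = gf, sigma = sigma)
  }
  predict_all <- function(p) {
    switch(model,
      exponential = p$gf[idx] + (p$gi[idx] - p$gf[idx]) * exp(-t_all / p$tau),
      cdweibull   = p$gf[idx] + (p$gi[idx] - p$gf[idx]) *
        exp(-exp(p$lam * (lt_all - log(p$tau)))),
      sigmoidal   = p$gi[idx] + (p$gf[idx] - p$gi[idx]) *
        exp(-exp((p$lam - t_all) / p$tau + 1))
    )
  }
  lp <- function(th) {
    p <- unpack(th)
    if (any(p$gi < 0) || any(p$gf < 0)) return(-Inf)
    lprior <- stats::dnorm(log(p$tau), pr$tau_meanlog, pr$tau_sdlog, log = TRUE)
    if (has_lam) {
      lprior <- lprior + if (model == "cdweibull") {
        stats::dnorm(log(p$lam), pr$lam_meanlog, pr$lam_sdlog, log = TRUE)
      } else {
        # half-normal on lam, sampled on the log scale (Jacobian log lam)
        stats::dnorm(p$lam, 0, pr$lam_halfnormal_sd, log = TRUE) + log(2) + log(p$lam)
      }
    }
    if (joint) {
      lprior <- lprior +
        sum(stats::dnorm(p$gi, init$gi, pr$endpoint_sd, log = TRUE)) +
        sum(stats::dnorm(p$gf, init$gf, pr$endpoint_sd, log = TRUE))
    }
    lprior <- lprior + stats::dnorm(p$sigma, 0, pr$sigma_halfnormal_sd, log = TRUE) +
      log(2) + log(p$sigma)
    mu <- predict_all(p)
    ll <- -length(y_all) * (0.5 * log(2 * pi) + log(p$sigma)) -
      sum((y_all - mu)^2) / (2 * p$sigma^2)
    lprior + ll
  }
  th0 <- c(log(init$tau), if (has_lam) log(if (model == "cdweibull") 1.2 else init$tau / 5),
           if (joint) c(init$gi, init$gf), log(init$sigma))

  attempts <- list(
    c(w = cfg$n_warmup, s = cfg$n_sampling),
    c(w = cfg$n_warmup_escalated, s = 2L * cfg$n_sampling),
    c(w = cfg$n_warmup_escalated, s = 4L * cfg$n_sampling)
  )[seq_len(cfg$max_attempts)]

  pre <- laplace_precondition(lp, th0)
  converged <- FALSE
  for (a in seq_along(attempts)) {
    res <- run_mcmc(lp, pre$mode,
                    n_chains = cfg$n_chains,
                    n_warmup = as.integer(attempts[[a]]["w"]),
                    n_sampling = as.integer(attempts[[a]]["s"]),
                    seed = cfg$seed + 1000L * (a - 1L),
                    target_accept = cfg$target_accept,
                    prop_chol = pre$chol_cov)
    # natural-scale draws
    draws <- t(apply(res$draws, 1L, function(th) {
      p <- unpack(th)
      c(p$tau, if (has_lam) p$lam, if (joint) c(p$gi, p$gf), p$sigma)
    }))
    colnames(draws) <- nm
    dtab <- diag_table(draws, res$n_chains)
    converged <- all(dtab$ess > cfg$ess_threshold) && all(dtab$rhat < cfg$rhat_max)
    if (converged) break
  }

  qs <- t(apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975)))
  summ <- data.frame(
    param = nm,
    mean = colMeans(draws),
    sd = apply(draws, 2L, stats::sd),
    q2.5 = qs[, 1L], q97.5 = qs[, 2L],
    ess = dtab$ess, rhat = dtab$rhat,
    row.names = NULL, stringsAsFactors = FALSE
  )

  fit <- structure(list(
    model = model, set_id = set_id, direction = dirs[1L],
    draws = draws, summary = summ, n_curves = K,
    points = pts, joint_endpoints = joint,
    fixed_gi = if (!joint) init$gi, fixed_gf = if (!joint) init$gf,
    n_divergent = 0L, converged = converged, attempts_used = a,
    accept_rate = res$accept_rate, seed = cfg$seed, config = cfg
  ), class = "kinetic_fit")
  fit$rmse <- fit_rmse(fit)
  fit
}

#' Posterior-mean parameters of a fit, per curve
#' @param fit a [fit_set()] result.
#' @param curve curve index within the set.
#' @return a [kinetic_params()] at the posterior means.
#' @export
fit_params <- function(fit, curve = 1L) {
  stopifnot(inherits(fit, "kinetic_fit"))
  m <- fit$summary$mean
  names(m) <- fit$summary$param
  gi <- if (fit$joint_endpoints) m[[paste0("g_i[", curve, "]")]] else fit$fixed_gi[curve]
  gf <- if (fit$joint_endpoints) m[[paste0("g_f[", curve, "]")]] else fit$fixed_gf[curve]
  kinetic_params(fit$model, g_i = max(gi, 0), g_f = max(gf, 0), tau = m[["tau"]],
                 lam = if (fit$model == "exponential") NULL else m[["lam"]])
}

#' Root-mean-squared error of a fitted set
#'
#' RMSE between the posterior-mean prediction and the observed gs, pooled
#' over all points of the set (mol m-2 s-1).
#'
#' @param fit a [fit_set()] result.
#' @return RMSE (mol m-2 s-1).
#' @export
fit_rmse <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  resid2 <- unlist(lapply(seq_len(fit$n_curves), function(k) {
    p <- fit$points[[k]]
    (p$gs - predict_gs(fit_params(fit, k), p$time))^2
  }))
  sqrt(mean(resid2))
}

#' Diagnostics report for a fitted set
#'
#' @param fit a [fit_set()] result.
#' @param cfg a [fit_config()] (defaults to the fit's own).
#' @return list with the per-parameter diagnostic table, divergence count,
#'   `verdict` (`"pass"`/`"fail"`) and `notes`.
#' @export
diagnose_fit <- function(fit, cfg = fit$config) {
  stopifnot(inherits(fit, "kinetic_fit"))
  d <- fit$summary[, c("param", "ess", "rhat")]
  bad_ess <- d$param[d$ess <= cfg$ess_threshold]
  bad_rhat <- d$param[d$rhat >= cfg$rhat_max]
  notes <- character(0)
  if (length(bad_ess)) notes <- c(notes, paste0("low ESS: ", paste(bad_ess, collapse = ", ")))
  if (length(bad_rhat)) notes <- c(notes, paste0("high R-hat: ", paste(bad_rhat, collapse = ", ")))
  # identifiability: a posterior for log tau nearly as wide as its prior
  # means the data carry no response information
  unidentified <- stats::sd(log(fit$draws[, "tau"])) > 0.8 * cfg$priors$tau_sdlog
  if (unidentified) {
    notes <- c(notes, "tau unidentified: posterior width close to the prior (no response information in data?)")
  }
  list(table = d, n_divergent = fit$n_divergent,
       verdict = if (length(bad_ess) + length(bad_rhat) == 0L && !unidentified)
         "pass" else "fail",
       notes = notes)
}

#' Pointwise log-likelihood matrix of a fit
#'
#' One row per posterior draw, one column per observed point of the set;
#' the input to [psis_loo()].
#'
#' @param fit a [fit_set()] result.
#' @return matrix (draws x points).
#' @export
loglik_matrix <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  dr <- fit$draws
  S <- nrow(dr)
  K <- fit$n_curves
  t_all <- unlist(lapply(fit$points, `[[`, "time"))
  y_all <- unlist(lapply(fit$points, `[[`, "gs"))
  idx <- rep(seq_len(K), vapply(fit$points, nrow, 0L))
  gi_m <- if (fit$joint_endpoints) dr[, paste0("g_i[", seq_len(K), "]"), drop = FALSE] else
    matrix(fit$fixed_gi, S, K, byrow = TRUE)
  gf_m <- if (fit$joint_endpoints) dr[, paste0("g_f[", seq_len(K), "]"), drop = FALSE] else
    matrix(fit$fixed_gf, S, K, byrow = TRUE)
  tau <- dr[, "tau"]
  sig <- dr[, "sigma"]
  lam <- if (fit$model == "exponential") NULL else dr[, "lam"]

  GI <- gi_m[, idx, drop = FALSE]
  GF <- gf_m[, idx, drop = FALSE]
  TT <- matrix(t_all, S, length(t_all), byrow = TRUE)
  EE <- switch(fit$model,
    exponential = exp(-TT / tau),
    cdweibull   = exp(-exp(lam * (log(pmax(TT, 1e-12)) - log(tau)))),
    sigmoidal   = NULL
  )
  MU <- if (fit$model == "sigmoidal") {
    GI + (GF - GI) * exp(-exp((lam - TT) / tau + 1))
  } else {
    GF + (GI - GF) * EE
  }
  YY <- matrix(y_all, S, length(y_all), byrow = TRUE)
  -0.5 * log(2 * pi) - log(sig) - (YY - MU)^2 / (2 * sig^2)
}

#' Compare fitted models of one set by PSIS-LOO
#'
#' Ranks >= 2 fits of the same data by LOOIC, with the pairwise standard
#' error of the pointwise elpd difference against the best model and a
#' `2 * SE` equivalence flag.
#'
#' @param fits list of [fit_set()] results on identical points.
#' @return data frame of class `"stomkin_loo_compare"`, best model first:
#'   `model`, `looic`, `se_looic`, `d_looic` (vs best), `se_diff`,
#'   `equivalent` (`d_looic < 2 * se_diff`), `unreliable`.
#' @export
loo_compare <- function(fits) {
  stopifnot(length(fits) >= 2L)
  npts <- vapply(fits, function(f) sum(vapply(f$points, nrow, 0L)), 0L)
  if (length(unique(npts)) != 1L) {
    stop("fits must be on identical data points", call. = FALSE)
  }
  loos <- lapply(fits, function(f) psis_loo(loglik_matrix(f)))
  looic <- vapply(loos, `[[`, 0.0, "looic")
  ord <- order(looic)
  best <- loos[[ord[1L]]]
  out <- do.call(rbind, lapply(ord, function(j) {
    di <- loos[[j]]$elpd_i - best$elpd_i
    se_diff <- sqrt(length(di) * stats::var(di))
    data.frame(
      model = vapply(fits, `[[`, "", "model")[j],
      looic = loos[[j]]$looic,
      se_looic = loos[[j]]$se_looic,
      d_looic = loos[[j]]$looic - best$looic,
      se_diff = se_diff,
      equivalent = (loos[[j]]$looic - best$looic) < pmax(2 * se_diff, 1e-9),
      unreliable = loos[[j]]$unreliable,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("stomkin_loo_compare", "data.frame")
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit: %s, %d curves, %s> %s (RMSE %.4g)\n",
              x$model, x$n_curves, x$direction,
              if (x$converged) "converged" else "NOT CONVERGED", x$rmse))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write fit results to a parameter table and JSON sidecar
#'
#' One CSV row per set x parameter (mean, sd, quantiles, ESS, R-hat) plus a
#' JSON sidecar recording model, seed and sampler configuration.
#'
#' @param fits list of [fit_set()] results.
#' @param path CSV output path; the sidecar gets extension `.json`.
#' @export
write_fit_results <- function(fits, path) {
  tab <- do.call(rbind, lapply(fits, function(f) {
    cbind(set_id = f$set_id, model = f$model, direction = f$direction,
          f$summary, rmse = f$rmse, converged = f$converged)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  side <- lapply(fits, function(f) list(
    set_id = f$set_id, model = f$model, seed = f$seed,
    n_chains = f$config$n_chains, n_warmup = f$config$n_warmup,
    n_sampling = f$config$n_sampling, attempts_used = f$attempts_used,
    converged = f$converged
  ))
  jsonlite::write_json(side, sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
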