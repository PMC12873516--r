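#' Construct a gs time-course object
#'
#' A gs time course is a data frame with columns `time` (s, strictly
#' increasing), `ppfd` (photon flux density, umol m-2 s-1), `gs`
#' (mol m-2 s-1), an optional `source_id`, and a `point_label` column
#' partitioning the series into `PRE_STEP`, `EXCLUDED_TRANSIENT`,
#' `RESPONSE` and `STEADY` points once curated.
#'
#' @param time,ppfd,gs numeric vectors of equal length.
#' @param source_id opaque identifier (publication/genotype/replicate).
#' @return a data frame of class `"gs_timecourse"`.
#' @export
gs_timecourse <- function(time, ppfd, gs, source_id = "tc") {
  stopifnot(is.numeric(time), is.numeric(ppfd), is.numeric(gs),
            length(time) == length(ppfd), length(time) == length(gs))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (any(gs < 0, na.rm = TRUE)) stop("gs must be non-negative", call. = FALSE)
  out <- data.frame(
    time = time, ppfd = ppfd, gs = gs,
    point_label = rep("PRE_STEP", length(time)),
    source_id = source_id,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gs_timecourse", "data.frame")
  out
}

# column alias maps for reading foreign gas-exchange exports
.tc_aliases <- list(
  time = c("time", "time_s", "elapsed", "secs"),
  ppfd = c("ppfd", "par", "qin", "light", "parin"),
  gs   = c("gs", "gsw", "cond", "conductance")
)

#' Read a gs time-course CSV
#'
#' Accepts the common column spellings of gas-exchange exports (`PPFD`,
#' `PAR`, `Qin` for light; `gs`, `gsw`, `Cond` for conductance), mapped
#' case-insensitively; extra alias spellings can be supplied.
#'
#' @param path CSV file path.
#' @param aliases named list extending the built-in alias map
#'   (names `time`, `ppfd`, `gs`).
#' @param source_id identifier recorded on the series; defaults to the file
#'   name.
#' @return a [gs_timecourse()].
#' @export
read_timecourse_csv <- function(path, aliases = list(), source_id = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE)
  amap <- .tc_aliases
  for (nm in names(aliases)) amap[[nm]] <- unique(c(amap[[nm]], tolower(aliases[[nm]])))
  pick <- function(field) {
    hit <- which(tolower(names(raw)) %in% amap[[field]])
    if (length(hit) == 0L) {
      stop(sprintf("no column matching '%s' (aliases: %s) in %s",
                   field, paste(amap[[field]], collapse = ", "), path),
           call. = FALSE)
    }
    col <- raw[[hit[1L]]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      if (length(bad)) {
        stop(sprintf("non-numeric '%s' values in %s at row(s) %s",
                     field, path, paste(utils::head(bad, 5L), collapse = ", ")),
             call. = FALSE)
      }
      col <- as.numeric(col)
    }
    col
  }
  gs_timecourse(pick("time"), pick("ppfd"), pick("gs"),
                source_id = source_id %||% basename(path))
}

#' Write a (possibly labelled) gs time course to CSV
#' @param tc a [gs_timecourse()].
#' @param path output file path.
#' @export
write_timecourse_csv <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect step changes in light intensity
#'
#' Finds contiguous changes in PPFD exceeding `min_delta` and reports one
#' light step per change, with direction set by the sign of the change.
#' A multi-sample ramp is merged into a single step anchored at its first
#' sample.
#'
#' @param tc a [gs_timecourse()].
#' @param min_delta minimum |PPFD change| (umol m-2 s-1) to count as a step.
#' @return data frame with columns `switch_time`, `ppfd_before`,
#'   `ppfd_after`, `direction` (`"INCREASE"`/`"DECREASE"`); zero rows when
#'   no step is present.
#' @export
detect_light_steps <- function(tc, min_delta = 50) {
  stopifnot(inherits(tc, "gs_timecourse"))
  d <- diff(tc$ppfd)
  changing <- abs(d) > 1e-9
  steps <- list()
  i <- 1L
  while (i <= length(d)) {
    if (changing[i]) {
      j <- i
      while (j < length(d) && changing[j + 1L] && sign(d[j + 1L]) == sign(d[i])) j <- j + 1L
      total <- tc$ppfd[j + 1L] - tc$ppfd[i]
      if (abs(total) >= min_delta) {
        steps[[length(steps) + 1L]] <- data.frame(
          switch_time = tc$time[i + 1L],
          ppfd_before = tc$ppfd[i],
          ppfd_after = tc$ppfd[j + 1L],
          direction = if (total > 0) "INCREASE" else "DECREASE",
          stringsAsFactors = FALSE
        )
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(steps) == 0L) {
    return(data.frame(switch_time = numeric(0), ppfd_before = numeric(0),
                      ppfd_after = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, steps)
}

#' Extract the response segment following one light step
#'
#' The segment runs from the switch to the next light step or the series
#' end. If a steady state is reached before the end point, later secondary
#' drifts are cut: steady state is declared where the rolling slope of gs
#' stays below `steady_slope` over a `steady_window`, and the segment is
#' truncated once the series leaves that steady band again. The retained
#' steady tail is trimmed to about `steady_trim` (default 5 min) beyond the
#' point where steady state is first reached.
#'
#' @param tc a [gs_timecourse()].
#' @param step one row of [detect_light_steps()] output.
#' @param all_steps full [detect_light_steps()] output for `tc`.
#' @param min_points minimum usable segment length (samples).
#' @param steady_slope |dgs/dt| threshold (mol m-2 s-2) for steady state.
#' @param steady_window window (s) over which the slope is assessed.
#' @param steady_trim steady tail length (s) retained after steady state.
#' @return a list of class `"response_segment"` with elements `step`,
#'   `data` (the labelled slice, including a 5-min pre-step window),
#'   `pre_steady_gs`, `steady_tail_duration`, `usable`, `flags`.
#' @export
extract_segment <- function(tc, step, all_steps, min_points = 10L,
                            steady_slope = 1e-5, steady_window = 300,
                            steady_trim = 300) {
  stopifnot(inherits(tc, "gs_timecourse"))
  t_sw <- step$switch_time
  later <- all_steps$switch_time[all_steps$switch_time > t_sw]
  t_end <- if (length(later)) min(later) else max(tc$time)

  pre <- tc[tc$time < t_sw & tc$time >= t_sw - 300, , drop = FALSE]
  pre_steady <- if (nrow(pre)) stats::median(pre$gs) else NA_real_

  seg <- tc[tc$time >= t_sw & tc$time <= t_end, , drop = FALSE]
  if (length(later)) seg <- seg[seg$time < t_end, , drop = FALSE]

  flags <- character(0)
  if (nrow(seg) < min_points) {
    return(structure(list(step = step, data = seg, pre_steady_gs = pre_steady,
                          steady_tail_duration = 0, usable = FALSE,
                          flags = "too_short"),
                     class = "response_segment"))
  }

  # steady-state onset: first time the rolling slope over steady_window
  # stays below steady_slope
  ts <- seg$time - t_sw
  onset <- NA_real_
  for (k in seq_len(nrow(seg))) {
    win <- which(ts >= ts[k] & ts <= ts[k] + steady_window)
    if (length(win) < 3L) break
    sl <- stats::coef(stats::lm.fit(cbind(1, ts[win]), seg$gs[win]))[2L]
    if (abs(sl) < steady_slope) { onset <- ts[k]; break }
  }

  if (!is.na(onset)) {
    steady_gs <- stats::median(seg$gs[ts >= onset & ts <= onset + steady_window])
    band <- max(0.02 * abs(steady_gs - pre_steady), 5 * steady_slope * steady_window)
    after <- which(ts > onset + steady_window & abs(seg$gs - steady_gs) > band)
    cut_at <- if (length(after)) ts[after[1L]] else Inf
    keep_until <- min(cut_at, onset + max(steady_trim, steady_window), max(ts))
    if (is.finite(cut_at)) flags <- c(flags, "secondary_drift_cut")
    seg <- seg[ts <= keep_until, , drop = FALSE]
    tail_dur <- keep_until - onset
  } else {
    tail_dur <- 0
    flags <- c(flags, "no_steady_state")
  }

  seg$point_label <- ifelse(!is.na(onset) & (seg$time - t_sw) >= onset, "STEADY", "RESPONSE")
  out <- rbind(
    within(pre, point_label <- "PRE_STEP"),
    seg
  )
  class(out) <- c("gs_timecourse", "data.frame")
  structure(list(
    step = step, data = out, pre_steady_gs = pre_steady,
    steady_tail_duration = tail_dur,
    usable = nrow(seg) >= min_points && (tail_dur >= steady_trim || !length(flags)),
    flags = flags
  ), class = "response_segment")
}

#' @export
print.response_segment <- function(x, ...) {
  cat(sprintf(
    "<response_segment: %s at t=%gs> %d points, steady tail %gs%s%s\n",
    x$step$direction, x$step$switch_time,
    sum(x$data$point_label %in% c("RESPONSE", "STEADY", "EXCLUDED_TRANSIENT")),
    x$steady_tail_duration,
    if (x$usable) "" else " [UNUSABLE]",
    if (length(x$flags)) paste0(" flags: ", paste(x$flags, collapse = ",")) else ""
  ))
  invisible(x)
}

#' Strip post-switch measurement transients from a segment
#'
#' A light switch perturbs cuvette temperature and vapour pressure deficit,
#' producing transient apparent gs excursions that do not reflect pore
#' aperture. Points after the switch are excluded up to the first point
#' that (a) lies within `tolerance` of the pre-step steady gs (fraction of
#' the segment's |dgs| estimate) and (b) is followed by a run of at least
#' `run_length` samples trending in the expected direction.
#'
#' @param seg a [extract_segment()] result.
#' @param tolerance fraction of |dgs| within which a point counts as
#'   "back at pre-step gs" (default 0.1).
#' @param run_length length of the directional run required after the
#'   anchor point (default 3).
#' @return the segment with `EXCLUDED_TRANSIENT` labels applied; if no
#'   qualifying anchor exists the whole segment is flagged `unusable`.
#' @export
strip_transients <- function(seg, tolerance = 0.1, run_length = 3L) {
  stopifnot(inherits(seg, "response_segment"))
  d <- seg$data
  post <- which(d$point_label %in% c("RESPONSE", "STEADY", "EXCLUDED_TRANSIENT"))
  if (!length(post) || is.na(seg$pre_steady_gs)) return(seg)
  gs <- d$gs[post]
  dir_sign <- if (seg$step$direction == "INCREASE") 1 else -1

  # dgs estimate: steady tail (or segment end) vs pre-step steady gs
  g_end <- stats::median(gs[max(1L, length(gs) - 5L):length(gs)])
  dgs <- g_end - seg$pre_steady_gs
  tol_abs <- tolerance * max(abs(dgs), 1e-6)

  anchor <- NA_integer_
  for (k in seq_along(gs)) {
    if (abs(gs[k] - seg$pre_steady_gs) <= tol_abs) {
      run <- gs[k:min(length(gs), k + run_length)]
      # "clear response": no counter-movement beyond half the tolerance
      # (rejects oscillating artifacts without demanding strict
      # monotonicity of a noisy, possibly lagged response)
      if (length(run) > run_length &&
          all(dir_sign * diff(run) > -0.5 * tol_abs)) {
        anchor <- k
        break
      }
    }
  }
  if (is.na(anchor)) {
    # a fast response may have moved slightly past tolerance by the first
    # sample; accept it only when still near the pre-step level AND cleanly
    # trending -- otherwise the artifact never recovered
    run <- gs[1:min(length(gs), 1L + run_length)]
    if (abs(gs[1L] - seg$pre_steady_gs) <= 3 * tol_abs &&
        length(run) > run_length && all(dir_sign * diff(run) > -1e-12)) {
      anchor <- 1L
    } else {
      seg$usable <- FALSE
      seg$flags <- unique(c(seg$flags, "transient_never_recovered"))
      return(seg)
    }
  }
  if (anchor > 1L) {
    d$point_label[post[seq_len(anchor - 1L)]] <- "EXCLUDED_TRANSIENT"
    # relabel the rest in case a previous pass excluded differently
    keep <- post[anchor:length(post)]
    steady <- d$point_label[keep] == "STEADY"
    d$point_label[keep] <- ifelse(steady, "STEADY", "RESPONSE")
  }
  seg$data <- d
  seg$flags <- setdiff(seg$flags, "transient_never_recovered")
  seg
}

#' Curate a raw time course end to end
#'
#' Convenience wrapper: detect light steps, extract the segment after each,
#' and strip post-switch transients.
#'
#' @inheritParams detect_light_steps
#' @inheritParams strip_transients
#' @param ... passed to [extract_segment()].
#' @return list of [extract_segment()] results (one per detected step).
#' @export
curate_timecourse <- function(tc, min_delta = 50, tolerance = 0.1,
                              run_length = 3L, ...) {
  steps <- detect_light_steps(tc, min_delta = min_delta)
  if (nrow(steps) == 0L) return(list())
  lapply(seq_len(nrow(steps)), function(i) {
    strip_transients(
      extract_segment(tc, steps[i, , drop = FALSE], steps, ...),
      tolerance = tolerance, run_length = run_length
    )
  })
}

#' Response-phase points of a segment
#'
#' Points contributing to the fit likelihood (`RESPONSE` and `STEADY`
#' labels), with time re-origined to the light switch.
#'
#' @param seg a [response_segment].
#' @return data frame with columns `time` (s since switch) and `gs`.
#' @export
segment_points <- function(seg) {
  stopifnot(inherits(seg, "response_segment"))
  d <- seg$data[seg$data$point_label %in% c("RESPONSE", "STEADY"), , drop = FALSE]
  data.frame(time = d$time - seg$step$switch_time, gs = d$gs)
}
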