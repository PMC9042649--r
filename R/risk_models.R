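#' Septic-shock probability as a function of time to treatment
#'
#' The probability of developing septic shock is a linear function of the
#' total hours to treatment `t` (relative to current-practice diagnosis,
#' negative = earlier). The line is anchored at the current-practice
#' prevalence `p_ref` at t = 0 and the assumed prevalence `p_early` at
#' `t_early` (base case: 56.6% at 0 h, 40% at -3 h, i.e. 5.5 percentage
#' points per hour), and is clamped to \[0,1\]. With `time_dependent = FALSE`
#' the prevalence is constant at `p_ref` for all t.
#'
#' @param line shock-risk line: list with `p_ref`, `p_early`, `t_early`,
#'   `time_dependent` (the `shock_risk` component of a config)
#' @param t hours to treatment (vectorised)
#' @return probability of septic shock at each `t`
#' @examples
#' shock_probability(default_base_case()$shock_risk, c(-3, 0, 3))
#' @export
shock_probability <- function(line, t) {
  if (!isTRUE(line$time_dependent)) {
    return(rep(line$p_ref, length(t)))
  }
  slope <- (line$p_ref - line$p_early) / abs(line$t_early)
  clamp01(line$p_ref + slope * t)
}

#' In-hospital mortality for patients with septic shock
#'
#' Under the default exponential model the mortality is
#' `a * exp(b * t)` (base case 0.4281 * exp(0.0272 t)), scaled by the PSA
#' relative-risk multiplier and clamped to \[0,1\]. Alternative models:
#' `"kumar"` (linear survival decrease per hour, anchored at 40% mortality at
#' t = 0) and `"lengquist"` (constant mortality independent of t).
#'
#' @param curves mortality-curve parameters (the `mortality` component of a
#'   config)
#' @param t hours to treatment (vectorised)
#' @return in-hospital mortality probability for septic-shock patients
#' @examples
#' mortality_shock(default_base_case()$mortality, c(-3, 0, 3))
#' @export
mortality_shock <- function(curves, t) {
  base <- switch(curves$model,
    exponential_linear = curves$a * exp(curves$b * t),
    kumar = curves$kumar_mortality_at_0 + curves$kumar_slope_per_hour * t,
    lengquist = rep(curves$lengquist_shock, length(t)),
    stop("unknown mortality model: ", curves$model)
  )
  clamp01(curves$rr_shock_multiplier * base)
}

#' In-hospital mortality for sepsis patients without septic shock
#'
#' Linear in the delay, `c * t`, floored at 0 for t <= 0 (earlier treatment
#' cannot produce negative mortality) and clamped to \[0,1\]. The
#' `"lengquist"` model replaces this by a constant.
#'
#' @inheritParams mortality_shock
#' @return in-hospital mortality probability for non-shock sepsis patients
#' @export
mortality_nonshock <- function(curves, t) {
  base <- switch(curves$model,
    exponential_linear = pmax(0, curves$c * t),
    kumar = pmax(0, curves$c * t),
    lengquist = rep(curves$lengquist_nonshock, length(t)),
    stop("unknown mortality model: ", curves$model)
  )
  clamp01(curves$rr_noshock_multiplier * base)
}

#' Estimate cumulative mortality at grid time points from grouped data (step 1)
#'
#' Given grouped delay-to-treatment data (treatment-delay intervals with
#' patient and death counts), solves for the cumulative mortality fraction
#' m(t) at each grid time point by linear programming: minimise the total
#' absolute deviation between implied and observed interval death counts,
#' subject to 0 <= m(t) <= 1 and m non-decreasing in t. The implied death
#' count of an interval is its patient count times the mean of m over the
#' grid points falling inside the interval. A tiny secondary penalty on
#' the sum of m makes the solution unique where the objective is flat.
#'
#' @param data list with `intervals` (data.frame with columns
#'   `interval_start`, `interval_end`, `n_patients`, `n_deaths`) and `grid`
#'   (numeric vector of evaluation hours; every interval must contain at
#'   least one grid point)
#' @return data.frame with columns `t` and `mortality` (one row per grid
#'   point, sorted by `t`), with attribute `"objective"` holding the achieved
#'   total absolute count deviation.
#' @seealso [fit_mortality_curves()] for step 2,
#'   [generate_grouped_mortality()] for synthetic inputs.
#' @export
estimate_mortality_points <- function(data) {
  iv <- data$intervals
  grid <- sort(unique(data$grid))
  stopifnot(is.data.frame(iv), length(grid) >= 1)
  iv <- iv[order(iv$interval_start), ]
  if (any(iv$n_deaths < 0) || any(iv$n_deaths > iv$n_patients)) {
    stop("invalid grouped data: death counts must satisfy 0 <= deaths <= patients",
         call. = FALSE)
  }
  if (any(iv$interval_end[-nrow(iv)] > iv$interval_start[-1] + 1e-9)) {
    stop("invalid grouped data: intervals must be non-overlapping and ordered",
         call. = FALSE)
  }
  G <- length(grid)
  I <- nrow(iv)
  members <- lapply(seq_len(I), function(i) {
    which(grid >= iv$interval_start[i] - 1e-9 & grid <= iv$interval_end[i] + 1e-9)
  })
  if (any(lengths(members) == 0)) {
    stop("grid does not cover every interval", call. = FALSE)
  }

  # variables: m_1..m_G, e_plus_1..I, e_minus_1..I  (all >= 0)
  nv <- G + 2 * I
  eps <- 1e-6
  obj <- c(rep(eps, G), rep(1, 2 * I))

  A1 <- matrix(0, G + (G - 1), nv)  # m_j <= 1; m_j - m_{j+1} <= 0
  b1 <- c(rep(1, G), rep(0, max(0, G - 1)))
  for (j in seq_len(G)) A1[j, j] <- 1
  if (G > 1) {
    for (j in seq_len(G - 1)) {
      A1[G + j, j] <- 1
      A1[G + j, j + 1] <- -1
    }
  }
  A3 <- matrix(0, I, nv)
  b3 <- iv$n_deaths
  for (i in seq_len(I)) {
    A3[i, members[[i]]] <- iv$n_patients[i] / length(members[[i]])
    A3[i, G + i] <- -1          # e_plus
    A3[i, G + I + i] <- 1       # e_minus
  }
  sol <- boot::simplex(a = obj, A1 = A1, b1 = b1, A3 = A3, b3 = b3,
                       maxi = FALSE, n.iter = 50 * nv, eps = 1e-10)
  if (sol$solved < 0) stop("linear program did not solve", call. = FALSE)
  m <- pmin(1, pmax(0, as.numeric(sol$soln[seq_len(G)])))
  out <- data.frame(t = grid, mortality = m)
  attr(out, "objective") <- sum(as.numeric(sol$soln[(G + 1):nv]))
  out
}

#' Fit a parametric mortality curve to point estimates (step 2)
#'
#' Fits either an exponential curve `a * exp(b t)` (least squares on the log
#' scale, closed form) or a line through the origin `c * t`
#' (slope = sum(t*y)/sum(t^2)) to the (t, mortality) point estimates from
#' [estimate_mortality_points()].
#'
#' @param points data.frame with columns `t` and `mortality` (>= 2 rows)
#' @param form `"exponential"` or `"linear_through_origin"`
#' @return named list of fitted coefficients: `a` and `b` for the
#'   exponential form, `c` for the linear form.
#' @export
fit_mortality_curves <- function(points,
                                 form = c("exponential", "linear_through_origin")) {
  form <- match.arg(form)
  stopifnot(is.data.frame(points), nrow(points) >= 2)
  t <- points$t
  y <- points$mortality
  if (form == "exponential") {
    bad <- which(y <= 0)
    if (length(bad) > 0) {
      stop("exponential fit requires positive mortalities; offending t = ",
           paste(t[bad], collapse = ", "), call. = FALSE)
    }
    fit <- stats::lm.fit(cbind(1, t), log(y))
    list(a = unname(exp(fit$coefficients[1])), b = unname(fit$coefficients[2]))
  } else {
    if (all(t == 0)) stop("linear fit through origin needs nonzero t", call. = FALSE)
    list(c = sum(t * y) / sum(t^2))
  }
}

#' Read / write grouped delay-vs-mortality data as CSV
#'
#' CSV columns: `interval_start`, `interval_end`, `n_patients`, `n_deaths`.
#'
#' @param path file path
#' @param data list with `intervals` data.frame (and optionally `grid`)
#' @param grid evaluation grid to attach on read (default: interval midpoints)
#' @return `read_grouped_mortality` returns a list with `intervals` and
#'   `grid`; `write_grouped_mortality` returns `path` invisibly.
#' @export
read_grouped_mortality <- function(path, grid = NULL) {
  iv <- utils::read.csv(path)
  need <- c("interval_start", "interval_end", "n_patients", "n_deaths")
  missing <- setdiff(need, names(iv))
  if (length(missing) > 0) {
    stop("grouped mortality CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(grid)) grid <- (iv$interval_start + iv$interval_end) / 2
  list(intervals = iv, grid = grid)
}

#' @rdname read_grouped_mortality
#' @export
write_grouped_mortality <- function(data, path) {
  utils::write.csv(data$intervals, path, row.names = FALSE)
  invisible(path)
}
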