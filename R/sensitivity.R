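#' Beta parameters from a point estimate and a symmetric range
#'
#' Reconstructs the `Beta(alpha, beta)` distribution whose mean is the
#' point estimate and whose standard deviation is a quarter of the stated
#' range (range = mean +/- 2 sd), via
#' `alpha + beta = m (1 - m) / sd^2 - 1`.
#'
#' @param mean Point estimate, a fraction in `(0, 1)`.
#' @param lo,hi Range endpoints, `0 < lo < mean < hi < 1`, symmetric about
#'   the mean.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' beta_params_from_range(0.57, 0.513, 0.627)  # about (171.4, 129.3)
#' @export
beta_params_from_range <- function(mean, lo, hi) {
  if (!(lo > 0 && lo < mean && mean < hi && hi < 1)) {
    stop("need 0 < lo < mean < hi < 1", call. = FALSE)
  }
  if (abs((mean - lo) - (hi - mean)) > 1e-6 * (hi - lo)) {
    stop("range must be symmetric about the mean", call. = FALSE)
  }
  sd <- (hi - lo) / 4
  nu <- mean * (1 - mean) / sd^2 - 1
  if (nu <= 0) {
    stop(sprintf("sd %g is too large for mean %g (alpha+beta would be <= 0)",
                 sd, mean), call. = FALSE)
  }
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Multivariate sensitivity specification
#'
#' Distributions for the uncertain constant inputs, one entry per
#' parameter: `list(dist = "beta", alpha =, beta =)`,
#' `list(dist = "normal", mu =, sigma =)`, or `list(dist = "fixed")` (kept
#' at the base value). Parameters not listed stay at their base values.
#'
#' @param params Named list of distribution entries; names must be
#'   [scalar_params()] fields.
#' @param n_runs Number of Monte-Carlo runs.
#' @param seed RNG seed.
#' @param method `"mc"` (independent Monte Carlo) or `"lhs"` (Latin
#'   hypercube, requires the `lhs` package).
#' @return A `sensitivity_spec` object.
#' @export
sensitivity_spec <- function(params, n_runs = 500, seed = 1234,
                             method = c("mc", "lhs")) {
  method <- match.arg(method)
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  bad <- setdiff(names(params), scalar_param_fields)
  if (length(bad)) {
    stop(sprintf("unknown parameter(s) in sensitivity spec: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(params)) {
    d <- params[[nm]]
    if (!d$dist %in% c("beta", "normal", "fixed")) {
      stop(sprintf("unknown distribution '%s' for %s", d$dist, nm),
           call. = FALSE)
    }
    if (d$dist == "beta" && (d$alpha <= 0 || d$beta <= 0)) {
      stop(sprintf("beta parameters for %s must be > 0", nm), call. = FALSE)
    }
    if (d$dist == "normal" && d$sigma < 0) {
      stop(sprintf("sigma for %s must be >= 0", nm), call. = FALSE)
    }
  }
  structure(list(params = params, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), method = method),
            class = "sensitivity_spec")
}

#' Bundled Hong Kong sensitivity specification
#'
#' The published multivariate design: Beta distributions for the four
#' `[0, 1]`-bounded behavioural fractions (parameterized as tabulated) and
#' a normal distribution for the unbounded elasticity `occu_dmd`; 500 runs
#' with seed 1234.
#'
#' @param n_runs,seed,method Overrides passed to [sensitivity_spec()].
#' @return A `sensitivity_spec`.
#' @export
hk_sensitivity_spec <- function(n_runs = 500, seed = 1234, method = "mc") {
  sensitivity_spec(list(
    use_hi = list(dist = "beta", alpha = 171.43, beta = 129.324),
    selfpay = list(dist = "beta", alpha = 375.94, beta = 5889.73),
    tax_dmd = list(dist = "beta", alpha = 36.547, beta = 228.285),
    severity_ftr = list(dist = "beta", alpha = 243.61, beta = 381.031),
    occu_dmd = list(dist = "normal", mu = 0.5, sigma = 0.025)
  ), n_runs = n_runs, seed = seed, method = method)
}

# draw an n_runs x n_params matrix of parameter values
sample_parameter_matrix <- function(spec, base_params) {
  nms <- names(spec$params)
  n <- spec$n_runs
  u <- NULL
  if (spec$method == "lhs") {
    if (!requireNamespace("lhs", quietly = TRUE)) {
      stop("method 'lhs' requires the lhs package", call. = FALSE)
    }
    u <- lhs::randomLHS(n, length(nms))
  }
  draws <- matrix(NA_real_, n, length(nms), dimnames = list(NULL, nms))
  for (j in seq_along(nms)) {
    d <- spec$params[[j]]
    draws[, j] <- switch(d$dist,
      beta = if (is.null(u)) stats::rbeta(n, d$alpha, d$beta) else
        stats::qbeta(u[, j], d$alpha, d$beta),
      normal = if (is.null(u)) stats::rnorm(n, d$mu, d$sigma) else
        stats::qnorm(u[, j], d$mu, d$sigma),
      fixed = rep(base_params[[nms[j]]], n))
  }
  draws
}

#' Draw one sampled parameter set
#'
#' Draws each parameter listed in the spec from its distribution and
#' leaves every other field of `base_params` untouched. Uses the current
#' RNG state; seed management belongs to the caller (see
#' [run_sensitivity()] for the seeded batch interface).
#'
#' @param spec A [sensitivity_spec()].
#' @param base_params A [scalar_params()].
#' @return A [scalar_params()] with sampled values.
#' @export
sample_parameter_set <- function(spec, base_params) {
  nms <- names(spec$params)
  for (nm in nms) {
    d <- spec$params[[nm]]
    base_params[[nm]] <- switch(d$dist,
      beta = stats::rbeta(1, d$alpha, d$beta),
      normal = stats::rnorm(1, d$mu, d$sigma),
      fixed = base_params[[nm]])
  }
  validate_scalar_params(base_params)
  base_params
}

#' Monte-Carlo sensitivity analysis with percentile envelopes
#'
#' Runs `n_runs` independent simulations, each with one sampled parameter
#' set held constant over the run, and summarizes the five model outputs
#' (`hi`, `pu_occu`, `pr_occu`, `pu_admit`, `pr_admit`) as pointwise
#' percentile curves.
#'
#' @param spec A [sensitivity_spec()].
#' @param base_params,inputs,policy,... As in [simulate_insurance()].
#' @param probs Percentile levels of the envelope.
#' @return A `sensitivity_envelope` list: `envelope` (long data frame with
#'   `date`, `output`, one column per percentile), `end_states` (per-run
#'   parameter draws and end-of-horizon outputs), `draws`, `spec`.
#' @export
run_sensitivity <- function(spec, base_params, inputs, policy = NULL,
                            probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                            ...) {
  outputs <- c("hi", "pu_occu", "pr_occu", "pu_admit", "pr_admit")
  set.seed(spec$seed)
  draws <- sample_parameter_matrix(spec, base_params)
  dots <- list(...)
  daily <- do.call(build_daily_inputs, c(list(
    inputs = inputs,
    calendar = if (is.null(dots$calendar)) surge_calendar() else
      dots$calendar,
    start = if (is.null(dots$start)) "2009-04-01" else dots$start,
    end = if (is.null(dots$end)) "2019-12-31" else dots$end),
    if (isTRUE(dots$interpolate)) list(interpolate = TRUE)))
  store <- NULL
  dates <- NULL
  for (r in seq_len(spec$n_runs)) {
    p <- base_params
    for (nm in colnames(draws)) p[[nm]] <- draws[r, nm]
    tryCatch(validate_scalar_params(p), error = function(e) {
      stop(sprintf("invalid draw in run %d (%s): %s", r,
                   paste(sprintf("%s=%.4g", colnames(draws), draws[r, ]),
                         collapse = ", "),
                   conditionMessage(e)), call. = FALSE)
    })
    traj <- simulate_insurance(p, inputs, policy = policy, ...,
                               .daily = daily)
    if (is.null(store)) {
      dates <- traj$date
      store <- lapply(outputs, function(o)
        matrix(NA_real_, nrow(traj), spec$n_runs))
      names(store) <- outputs
    }
    for (o in outputs) store[[o]][, r] <- traj[[o]]
  }
  qnames <- paste0("p", formatC(probs * 100, format = "g"))
  env <- do.call(rbind, lapply(outputs, function(o) {
    qs <- t(apply(store[[o]], 1, stats::quantile, probs = probs,
                  names = FALSE))
    df <- data.frame(date = dates, output = o)
    df[qnames] <- as.data.frame(qs)
    df
  }))
  last <- length(dates)
  ends <- data.frame(run = seq_len(spec$n_runs))
  ends <- cbind(ends, as.data.frame(draws))
  for (o in outputs) ends[[paste0("end_", o)]] <- store[[o]][last, ]
  structure(list(envelope = env, end_states = ends, draws = draws,
                 spec = spec, probs = probs),
            class = "sensitivity_envelope")
}

#' @export
print.sensitivity_envelope <- function(x, ...) {
  n <- x$spec$n_runs
  hi_end <- x$end_states$end_hi
  cat(sprintf("Sensitivity envelope: %d runs (seed %d, %s sampling)\n",
              n, x$spec$seed, x$spec$method))
  cat(sprintf("  end-of-horizon HI: median %.2f%%, 95%% band %.2f%% .. %.2f%%\n",
              100 * stats::median(hi_end),
              100 * stats::quantile(hi_end, 0.025, names = FALSE),
              100 * stats::quantile(hi_end, 0.975, names = FALSE)))
  invisible(x)
}

#' Write sensitivity outputs as CSV
#'
#' @param env A `sensitivity_envelope`.
#' @param envelope_path CSV for the percentile curves (or `NULL`).
#' @param end_states_path CSV for the per-run end-state table (or `NULL`).
#' @return `env` invisibly.
#' @export
write_sensitivity <- function(env, envelope_path = NULL,
                              end_states_path = NULL) {
  if (!is.null(envelope_path)) {
    df <- env$envelope
    df$date <- format(df$date, "%Y-%m-%d")
    utils::write.csv(df, envelope_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(end_states_path)) {
    utils::write.csv(env$end_states, end_states_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(env)
}

#' Band plot of a sensitivity envelope
#'
#' Time-series ribbons of the outer and interquartile percentile bands
#' around the median, in the style of multivariate sensitivity graphs.
#'
#' @param env A `sensitivity_envelope`.
#' @param output One of `"hi"`, `"pu_occu"`, `"pr_occu"`, `"pu_admit"`,
#'   `"pr_admit"`.
#' @return A ggplot object.
#' @export
plot_envelope <- function(env, output = "hi") {
  src <- env$envelope[env$envelope$output == output, ]
  qn <- names(src)[grep("^p", names(src))]
  df <- data.frame(date = src$date,
                   lo = src[[qn[1]]], hi = src[[qn[length(qn)]]],
                   mid_lo = src[[qn[2]]], mid_hi = src[[qn[length(qn) - 1]]],
                   med = src[[qn[ceiling(length(qn) / 2)]]])
  ggplot2::ggplot(df, ggplot2::aes(x = date)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mid_lo, ymax = mid_hi),
                         fill = "steelblue", alpha = 0.45) +
    ggplot2::geom_line(ggplot2::aes(y = med), color = "navy") +
    ggplot2::labs(x = NULL, y = output,
                  title = sprintf("Sensitivity envelope: %s", output))
}
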