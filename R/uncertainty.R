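# One-way (tornado) sensitivity analysis, probabilistic sensitivity analysis
# with CEAC, and clinic-TTR scenario analyses.

# Deterministic 31-bit string hash for per-parameter substreams: one master
# seed plus a path-derived offset, so adding a parameter never perturbs the
# draws of existing ones.
param_stream_seed <- function(path, seed, iteration) {
  h <- 0
  for (b in utf8ToInt(path)) h <- (h * 31 + b) %% 2147483647
  (h * 1009 + (seed %% 1048576) * 393241 + iteration * 769) %% 2147483646 + 1
}

moment_draw <- function(family, mean, se) {
  if (se == 0) return(mean)
  switch(family,
    gamma = {
      shape <- (mean / se)^2
      stats::rgamma(1L, shape = shape, scale = se^2 / mean)
    },
    beta = {
      if (mean <= 0 || mean >= 1)
        stop_domain(paste0("beta family needs a mean in (0,1), got ", mean))
      v <- se^2
      if (v >= mean * (1 - mean))
        stop_domain("beta family variance too large for its mean")
      a <- mean * (mean * (1 - mean) / v - 1)
      stats::rbeta(1L, a, a * (1 - mean) / mean)
    },
    lognormal = {
      sdlog <- sqrt(log(1 + (se / mean)^2))
      stats::rlnorm(1L, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
    },
    stop_domain(paste0("unknown distribution family: ", family)))
}

#' Draw one probabilistic parameter sample
#'
#' Every parameter carrying an uncertainty descriptor is drawn independently
#' from its assigned family (gamma for event rates, beta for utilities,
#' log-normal for costs), parameterized by method of moments from its point
#' estimate and standard error. Parameters without descriptors are left at
#' their base values. Draws are reproducible: each parameter has its own
#' stream derived from the master seed and the iteration number.
#'
#' @param params `nvaf_parameters` with `uncertainty` descriptors
#' @param seed master seed (integer)
#' @param iteration iteration number (>= 1)
#' @return a `nvaf_parameters` object with drawn values
#' @export
draw_psa_sample <- function(params, seed = 1L, iteration = 1L) {
  for (d in params$uncertainty) {
    m <- get_param(params, d$path)
    if (d$se == 0 || m == 0) next
    set.seed(param_stream_seed(d$path, seed, iteration))
    params <- set_param(params, d$path, moment_draw(d$family, m, d$se))
  }
  params
}

#' Probabilistic sensitivity analysis
#'
#' Evaluates both treatment arms on each of `iterations` joint parameter
#' draws (correlated sampling: the two arms always see the same draw) and
#' records the incremental cost and incremental QALY pair.
#'
#' @param params `nvaf_parameters`
#' @param iterations number of draws (default: the configured
#'   `psa_iterations`)
#' @param seed master seed
#' @param wtp_grid willingness-to-pay grid for the acceptability curve
#' @return object of class `nvaf_psa` with `draws` (data.frame of
#'   `d_cost`, `d_qaly`, `d_ly`), `ceac` (data.frame `wtp`, `probability`),
#'   `iterations`, `seed`
#' @export
run_psa <- function(params, iterations = NULL, seed = 1L,
                    wtp_grid = NULL) {
  if (is.null(iterations)) iterations <- params$settings$psa_iterations
  if (iterations < 1) stop_domain("iterations must be >= 1")
  if (is.null(wtp_grid)) wtp_grid <- params$settings$wtp_thresholds
  d_cost <- d_qaly <- d_ly <- numeric(iterations)
  for (i in seq_len(iterations)) {
    p <- draw_psa_sample(params, seed, i)
    edges <- model_edges(p)
    ref <- evaluate_arm(p, "apixaban", edges)
    com <- evaluate_arm(p, "vka", edges)
    d_cost[i] <- ref$cost$total - com$cost$total
    d_qaly[i] <- ref$qaly - com$qaly
    d_ly[i] <- ref$ly - com$ly
  }
  draws <- data.frame(d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly)
  out <- structure(list(draws = draws, iterations = iterations, seed = seed,
                        wtp_grid = wtp_grid, ceac = NULL),
                   class = "nvaf_psa")
  out$ceac <- ceac(out, wtp_grid)
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of draws whose net
#' monetary benefit `wtp * d_qaly - d_cost` is strictly positive.
#'
#' @param psa `nvaf_psa` object (or list with a `draws` data.frame)
#' @param wtp_grid non-empty numeric vector of thresholds (currency/QALY)
#' @return data.frame with columns `wtp` and `probability`
#' @export
ceac <- function(psa, wtp_grid) {
  if (length(wtp_grid) == 0L) stop_domain("WTP grid must be non-empty")
  d <- psa$draws
  prob <- vapply(wtp_grid, function(l) mean(l * d$d_qaly - d$d_cost > 0),
                 numeric(1L))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' @export
print.nvaf_psa <- function(x, ...) {
  cat(sprintf("<nvaf_psa> %d iterations (seed %d)\n", x$iterations, x$seed))
  cat(sprintf("  mean incremental cost %.0f, QALYs %.3f\n",
              mean(x$draws$d_cost), mean(x$draws$d_qaly)))
  for (i in seq_len(nrow(x$ceac)))
    cat(sprintf("  P(cost-effective at %0.f/QALY) = %.3f\n",
                x$ceac$wtp[i], x$ceac$probability[i]))
  invisible(x)
}

#' @export
plot.nvaf_psa <- function(x, which = c("plane", "ceac"), wtp_lines = NULL, ...) {
  which <- match.arg(which)
  if (which == "plane") {
    graphics::plot(x$draws$d_qaly, x$draws$d_cost, pch = 16, cex = 0.4,
                   col = grDevices::adjustcolor("#1b6ca8", 0.4),
                   xlab = "Incremental QALYs", ylab = "Incremental cost",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey60")
    if (is.null(wtp_lines)) wtp_lines <- x$wtp_grid
    for (l in wtp_lines) graphics::abline(0, l, lty = 2, col = "grey40")
  } else {
    grid <- seq(0, max(x$wtp_grid, 50000), length.out = 101L)
    cv <- ceac(x, grid)
    graphics::plot(cv$wtp, cv$probability, type = "l", lwd = 2, ylim = c(0, 1),
                   xlab = "Willingness to pay (per QALY)",
                   ylab = "Probability cost-effective",
                   main = "Cost-effectiveness acceptability curve", ...)
  }
  invisible(x)
}

#' One-way sensitivity sweep of a single parameter
#'
#' Reruns the full deterministic model twice with one parameter set to its
#' low and high value, all other parameters fixed.
#'
#' @param params `nvaf_parameters`
#' @param path dotted parameter path (see [get_param()])
#' @param low,high values on the parameter's natural scale, `low <= high`
#' @return list with `parameter`, `low`, `high`, `icer_low`, `icer_high`
#'   and the two `nvaf_ce_result` objects
#' @export
univariate_sweep <- function(params, path, low, high) {
  if (low > high) stop_domain("low bound exceeds high bound")
  get_param(params, path)  # errors on unresolvable path
  at <- function(v) nvaf_ce(set_param(params, path, v))$ce
  lo <- at(low); hi <- at(high)
  list(parameter = path, low = low, high = high,
       icer_low = lo$icer_per_qaly, icer_high = hi$icer_per_qaly,
       ce_low = lo, ce_high = hi)
}

default_tornado_set <- function(params) {
  c("rates.apixaban.ischemic_stroke", "rates.vka.ischemic_stroke",
    "rates.apixaban.other_discontinuation", "rates.vka.other_discontinuation",
    "rates.apixaban.ich", "rates.vka.ich",
    "rates.apixaban.other_mb", "rates.vka.other_mb",
    "rates.apixaban.mi", "rates.vka.mi",
    "utilities.af_baseline",
    "costs.drug_per_cycle.apixaban", "costs.routine_care_per_cycle",
    "costs.inr_monitoring_per_cycle")
}

#' Tornado (one-way) sensitivity analysis
#'
#' Sweeps each listed parameter between its 95% interval bounds (mean
#' +/- 1.96 SE from its uncertainty descriptor, clamped to the parameter's
#' domain) and records the ICER at both bounds.
#'
#' @param params `nvaf_parameters`
#' @param parameters character vector of parameter paths, or a data.frame
#'   with columns `path`, `low`, `high`; defaults to the key event-rate,
#'   utility and cost inputs
#' @return object of class `nvaf_tornado`: data.frame sorted by ICER spread,
#'   with the base-case ICER as attribute `base_icer`
#' @export
tornado <- function(params, parameters = NULL) {
  base <- nvaf_ce(params)$ce
  if (is.null(parameters)) parameters <- default_tornado_set(params)
  if (is.character(parameters)) {
    descr <- params$uncertainty
    paths <- vapply(descr, `[[`, "", "path")
    rows <- lapply(parameters, function(p) {
      i <- match(p, paths)
      if (is.na(i)) stop_domain(paste0("no uncertainty descriptor for ", p))
      m <- get_param(params, p); se <- descr[[i]]$se
      lo <- max(m - 1.96 * se, 0)
      hi <- m + 1.96 * se
      if (descr[[i]]$family == "beta") hi <- min(hi, 1)
      data.frame(path = p, low = lo, high = hi, stringsAsFactors = FALSE)
    })
    parameters <- do.call(rbind, rows)
  }
  res <- lapply(seq_len(nrow(parameters)), function(i) {
    sw <- univariate_sweep(params, parameters$path[i],
                           parameters$low[i], parameters$high[i])
    data.frame(parameter = sw$parameter, low = sw$low, high = sw$high,
               icer_low = sw$icer_low, icer_high = sw$icer_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$spread <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  structure(out, base_icer = base$icer_per_qaly,
            class = c("nvaf_tornado", "data.frame"))
}

#' @export
plot.nvaf_tornado <- function(x, ...) {
  n <- nrow(x)
  base <- attr(x, "base_icer")
  ord <- rev(seq_len(n))
  op <- graphics::par(mar = c(4, 14, 3, 1))
  on.exit(graphics::par(op))
  rng <- range(c(x$icer_low, x$icer_high, base), na.rm = TRUE)
  graphics::plot(NA, xlim = rng, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "ICER per QALY", ylab = "",
                 main = "One-way sensitivity (tornado)")
  graphics::axis(2, at = seq_len(n), labels = x$parameter[ord], las = 1,
                 cex.axis = 0.7)
  for (i in seq_len(n)) {
    r <- x[ord[i], ]
    graphics::segments(min(r$icer_low, r$icer_high),
                       i, max(r$icer_low, r$icer_high), i, lwd = 8,
                       col = "#1b6ca8")
  }
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

#' Default clinic-TTR scenario set
#'
#' The three alternative cTTR strata plus equal distribution of patients
#' across all strata.
#' @param params `nvaf_parameters`
#' @return list of scenario specs (`id`, `policy`)
#' @export
default_scenarios <- function(params) {
  st <- params$ttr_strata
  base_idx <- findInterval(params$cohort$mean_ttr, st$breaks,
                           rightmost.closed = TRUE)
  alt <- setdiff(seq_along(st$labels), base_idx)
  c(lapply(alt, function(i)
      list(id = st$labels[i], policy = list(type = "stratum", index = i))),
    list(list(id = "Equal distribution across cTTRs",
              policy = list(type = "equal_mix"))))
}

#' Scenario analyses over levels of INR control
#'
#' Re-resolves the four INR-control-dependent event rates under each
#' scenario's cTTR policy and reruns the full deterministic model.
#'
#' @param params `nvaf_parameters`
#' @param scenarios list of scenario specs (`id`, `policy`); defaults to
#'   [default_scenarios()]
#' @return object of class `nvaf_scenarios`: a data.frame with one row per
#'   scenario and arm, echoing the adjusted rates, per-arm totals,
#'   incrementals and ICERs; the fitted objects are kept in attribute
#'   `fits`
#' @export
run_scenarios <- function(params, scenarios = NULL) {
  if (is.null(scenarios)) scenarios <- default_scenarios(params)
  rows <- list(); fits <- list()
  for (sc in scenarios) {
    p <- params
    p$rates <- ttr_adjust_rates(params, sc$policy)
    fit <- nvaf_ce(p)
    fits[[sc$id]] <- fit
    for (arm in c("vka", "apixaban")) {
      a <- fit$arms[[arm]]
      first <- arm == "vka"
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$id, treatment = arm,
        is_rate = p$rates[[arm]]$ischemic_stroke,
        ich_rate = p$rates[[arm]]$ich,
        other_mb_rate = p$rates[[arm]]$other_mb,
        crnm_rate = p$rates[[arm]]$crnm,
        cost = a$cost$total, qaly = a$qaly, ly = a$ly,
        d_cost = if (first) fit$ce$d_cost else NA_real_,
        d_qaly = if (first) fit$ce$d_qaly else NA_real_,
        d_ly = if (first) fit$ce$d_ly else NA_real_,
        icer_per_qaly = if (first) fit$ce$icer_per_qaly else NA_real_,
        icer_per_ly = if (first) fit$ce$icer_per_ly else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, fits = fits, class = c("nvaf_scenarios", "data.frame"))
}
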