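#' Fit the cost-effectiveness model
#'
#' Central evaluator: runs the lifetime Markov cohort model for the
#' reference arm (apixaban) and the comparator arm (VKA) under one parameter
#' set and computes incremental discounted costs, QALYs, life years and the
#' ICER.
#'
#' @param params `nvaf_parameters` (e.g. from [reference_parameters()] or
#'   [load_model_config()])
#' @param reference,comparator initial therapies of the two arms
#' @return object of class `nvaf_ce` with elements `arms` (named list of
#'   `nvaf_arm`), `ce` (`nvaf_ce_result`) and `params`
#' @examples
#' fit <- nvaf_ce(reference_parameters())
#' summary(fit)
#' @export
nvaf_ce <- function(params, reference = "apixaban", comparator = "vka") {
  if (!inherits(params, "nvaf_parameters"))
    params <- as_nvaf_parameters(params)
  edges <- model_edges(params)
  arms <- list(evaluate_arm(params, reference, edges),
               evaluate_arm(params, comparator, edges))
  names(arms) <- c(reference, comparator)
  structure(list(arms = arms, ce = compute_icer(arms[[1L]], arms[[2L]]),
                 reference = reference, comparator = comparator,
                 params = params),
            class = "nvaf_ce")
}

#' @export
print.nvaf_ce <- function(x, ...) {
  ce <- x$ce
  cat(sprintf("Markov cohort cost-effectiveness: %s vs %s\n",
              x$reference, x$comparator))
  for (a in names(x$arms)) {
    arm <- x$arms[[a]]
    cat(sprintf("  %-9s cost %9.0f  QALYs %6.2f  LYs %6.2f\n",
                a, arm$cost$total, arm$qaly, arm$ly))
  }
  cat(sprintf("  incremental cost %.0f, QALYs %.2f, LYs %.2f\n",
              ce$d_cost, ce$d_qaly, ce$d_ly))
  if (ce$dominance == "tradeoff")
    cat(sprintf("  ICER %.0f /QALY, %.0f /LY\n", ce$icer_per_qaly, ce$icer_per_ly))
  else cat("  dominance:", ce$dominance, "\n")
  invisible(x)
}

#' @export
summary.nvaf_ce <- function(object, ...) {
  structure(list(ce_table = render_ce_summary(object$ce),
                 event_tables = lapply(object$arms, function(a)
                   render_event_cost_table(a$tally, a$cost)),
                 fit = object),
            class = "summary.nvaf_ce")
}

#' @export
print.summary.nvaf_ce <- function(x, ...) {
  cat("Cost-effectiveness summary\n\n")
  print(x$ce_table, row.names = FALSE)
  for (a in names(x$event_tables)) {
    cat("\nEvents per", format(x$fit$arms[[a]]$trace$cohort_size),
        "patients,", a, "arm\n")
    print(utils::head(x$event_tables[[a]], 12L), row.names = FALSE)
    if (nrow(x$event_tables[[a]]) > 12L)
      cat("  ... (", nrow(x$event_tables[[a]]) - 12L, "more rows )\n")
  }
  invisible(x)
}

#' @export
plot.nvaf_ce <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 1))
  on.exit(graphics::par(op))
  cols <- c("#1b6ca8", "#c84b31")
  first <- TRUE
  for (i in seq_along(x$arms)) {
    tr <- x$arms[[i]]$trace
    alive <- rowSums(tr$occupancy[, tr$info$alive, drop = FALSE]) / tr$cohort_size
    t <- c(tr$cycle_time, tr$cycle_time[length(tr$cycle_time)] + tr$cycle_years)
    if (first) {
      graphics::plot(t, alive, type = "l", col = cols[i], lwd = 2,
                     xlab = "Years in model", ylab = "Fraction alive",
                     main = "Cohort survival by arm", ylim = c(0, 1), ...)
      first <- FALSE
    } else graphics::lines(t, alive, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = names(x$arms), col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
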