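# Report rendering in the layouts used for published cohort summaries:
# event/cost breakdown per arm, CE summary, scenario grid. All numbers stay
# at full precision in the returned tables; rounding happens only in the
# format/print methods.

#' Render the per-arm event and cost breakdown
#'
#' Lifetime expected event counts per cohort together with the discounted
#' per-patient acute-event and treatment cost components, with "Sum" rows
#' computed from their sub-rows.
#'
#' @param tally named event tally from [tally_events()] (or an `nvaf_arm`)
#' @param cost cost accrual list from [accrue_costs()] (optional when an
#'   `nvaf_arm` is given)
#' @return data.frame of class `nvaf_report_table` with columns `label`,
#'   `events`, `acute_cost_pp`; treatment-cost rows carry `NA` events
#' @export
render_event_cost_table <- function(tally, cost = NULL) {
  if (inherits(tally, "nvaf_arm")) {
    cost <- tally$cost
    tally <- tally$tally
  }
  ac <- if (!is.null(cost)) cost$acute_by_event else
    stats::setNames(rep(NA_real_, length(tally)), names(tally))
  rows <- list()
  add <- function(label, events, costs = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(label = label, events = events,
                                             acute_cost_pp = costs,
                                             stringsAsFactors = FALSE)
  block <- function(title, keys, sublabels) {
    for (i in seq_along(keys)) add(paste0(title, ": ", sublabels[i]),
                                   tally[[keys[i]]], ac[[keys[i]]])
    add(paste0(title, ": Sum"), sum(tally[keys]), sum(ac[keys]))
  }
  sev_lab <- c("Mild, non-fatal", "Moderate, non-fatal", "Severe, non-fatal",
               "Fatal")
  block("IS", paste0("is_first_", c(severity_levels(), "fatal")), sev_lab)
  block("Recurrent IS", paste0("is_rec_", c(severity_levels(), "fatal")), sev_lab)
  block("HS", paste0("hs_first_", c(severity_levels(), "fatal")), sev_lab)
  block("Recurrent HS", paste0("hs_rec_", c(severity_levels(), "fatal")), sev_lab)
  block("SE", c("se_nonfatal", "se_fatal"), c("Non-fatal", "Fatal"))
  block("Other ICH", c("other_ich_nonfatal", "other_ich_fatal"),
        c("Non-fatal", "Fatal"))
  block("Other MBs", c("mb_gi_nonfatal", "mb_nongi_nonfatal", "mb_fatal"),
        c("Non-fatal GI bleedings", "Non-fatal non-GI", "Fatal"))
  add("CRNM bleeding", tally[["crnm"]], ac[["crnm"]])
  block("MI", c("mi_nonfatal", "mi_fatal"), c("Non-fatal", "Fatal"))
  add("Other treatment discontinuation", tally[["other_disc"]])
  if (!is.null(cost)) {
    add("Cost of anticoagulants", NA_real_, cost$breakdown[["drug"]])
    add("Cost of routine care", NA_real_, cost$breakdown[["routine_care"]])
    add("Cost of INR monitoring", NA_real_, cost$breakdown[["inr_monitoring"]])
    add("Long-term maintenance costs", NA_real_, cost$breakdown[["long_term"]])
    add("Total costs", NA_real_, cost$total)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nvaf_report_table", "data.frame")
  out
}

#' @export
format.nvaf_report_table <- function(x, ...) {
  data.frame(label = x$label,
             events = ifelse(is.na(x$events), "", sprintf("%.2f", x$events)),
             acute_cost_pp = ifelse(is.na(x$acute_cost_pp), "",
                                    sprintf("%.0f", x$acute_cost_pp)),
             stringsAsFactors = FALSE)
}

#' @export
print.nvaf_report_table <- function(x, ...) {
  print.data.frame(format(x), row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Render the cost-effectiveness summary table
#'
#' Per-arm totals, incrementals and ICERs. Displayed ICERs come from the
#' full-precision internals, never from re-dividing rounded cells; when no
#' trade-off exists the ICER cells hold dashes and the dominance label.
#'
#' @param ce `nvaf_ce_result`
#' @param seed,config_hash optional run metadata recorded as attributes
#' @return data.frame with one row per arm (formatted character cells)
#' @export
render_ce_summary <- function(ce, seed = NULL, config_hash = NULL) {
  eur <- function(x) sprintf("%.0f", x)
  two <- function(x) sprintf("%.2f", x)
  icer_cell <- function(v) if (is.na(v)) "-" else eur(v)
  ref <- ce$reference; com <- ce$comparator
  out <- data.frame(
    treatment = c(if (!is.null(com$arm)) com$arm else "comparator",
                  if (!is.null(ref$arm)) ref$arm else "reference"),
    cost = eur(c(com$cost$total, ref$cost$total)),
    qalys = two(c(com$qaly, ref$qaly)),
    lys = two(c(com$ly, ref$ly)),
    d_cost = c(eur(ce$d_cost), ""),
    d_qaly = c(two(ce$d_qaly), ""),
    d_lys = c(two(ce$d_ly), ""),
    icer_per_qaly = c(icer_cell(ce$icer_per_qaly), ""),
    icer_per_ly = c(icer_cell(ce$icer_per_ly), ""),
    stringsAsFactors = FALSE)
  if (ce$dominance != "tradeoff") out$icer_per_qaly[1L] <-
      paste0("- (", ce$dominance, ")")
  attr(out, "seed") <- seed
  attr(out, "config_hash") <- config_hash
  out
}

#' Stable content hash of a parameter set
#'
#' 31-bit rolling hash of the canonical YAML serialization; used for
#' provenance metadata in reports and logs.
#'
#' @param params `nvaf_parameters`
#' @return 8-character hex string
#' @export
config_hash <- function(params) {
  s <- yaml::as.yaml(as_config_list(unclass(params)), precision = 12L)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# -- command-line interface ---------------------------------------------------

cli_opts <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      out[[substring(a, 3L)]] <- if (i < length(args)) args[[i + 1L]] else ""
      i <- i + 2L
    } else i <- i + 1L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `fixtures` (write the reference configuration), `run`
#' (deterministic base case), `tornado`, `psa`, `scenarios`. Flags:
#' `--config <file>`, `--seed <int>`, `--iterations <n>`,
#' `--wtp <v1,v2,...>`, `--out <dir>`. Results are written as CSV into the
#' output directory together with a log recording the seed and
#' configuration hash.
#'
#' @param args character vector of command-line arguments
#' @return exit status: 0 success, 1 validation error, 2 runtime error
#' @export
nvafce_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: nvafce <fixtures|run|tornado|psa|scenarios> [--config f] [--seed n]\n",
        "             [--iterations n] [--wtp v1,v2] [--out dir]\n")
    return(invisible(2L))
  }
  cmd <- args[[1L]]
  o <- cli_opts(args[-1L])
  outdir <- if (!is.null(o$out)) o$out else "."
  seed <- if (!is.null(o$seed)) as.integer(o$seed) else 1L
  status <- tryCatch({
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    params <- if (!is.null(o$config)) load_model_config(o$config)
              else reference_parameters(seed)
    if (!is.null(o$wtp))
      params$settings$wtp_thresholds <-
        as.numeric(strsplit(o$wtp, ",")[[1L]])
    t0 <- proc.time()[["elapsed"]]
    hash <- config_hash(params)
    logline <- function(...) cat(..., "\n", sep = "",
                                 file = file.path(outdir, "nvafce.log"),
                                 append = TRUE)
    logline("command=", cmd, " seed=", seed, " config_hash=", hash)
    switch(cmd,
      fixtures = {
        write_model_config(params, file.path(outdir, "reference_config.yaml"))
      },
      run = {
        fit <- nvaf_ce(params)
        utils::write.csv(format(render_event_cost_table(fit$arms[[1L]])),
                         file.path(outdir, "events_apixaban.csv"), row.names = FALSE)
        utils::write.csv(format(render_event_cost_table(fit$arms[[2L]])),
                         file.path(outdir, "events_vka.csv"), row.names = FALSE)
        utils::write.csv(render_ce_summary(fit$ce, seed, hash),
                         file.path(outdir, "ce_summary.csv"), row.names = FALSE)
      },
      tornado = {
        tw <- tornado(params)
        utils::write.csv(as.data.frame(tw), file.path(outdir, "tornado.csv"),
                         row.names = FALSE)
      },
      psa = {
        iters <- if (!is.null(o$iterations)) as.integer(o$iterations)
                 else params$settings$psa_iterations
        ps <- run_psa(params, iterations = iters, seed = seed)
        utils::write.csv(ps$draws, file.path(outdir, "ce_plane.csv"),
                         row.names = FALSE)
        utils::write.csv(ps$ceac, file.path(outdir, "ceac.csv"),
                         row.names = FALSE)
      },
      scenarios = {
        sc <- run_scenarios(params)
        utils::write.csv(as.data.frame(sc), file.path(outdir, "scenarios.csv"),
                         row.names = FALSE)
      },
      stop_domain(paste0("unknown subcommand: ", cmd)))
    logline("runtime_s=", sprintf("%.2f", proc.time()[["elapsed"]] - t0))
    0L
  },
  nvafce_validation_error = function(e) {
    message("validation error: ", conditionMessage(e)); 1L
  },
  error = function(e) {
    message("error: ", conditionMessage(e)); 2L
  })
  invisible(status)
}
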