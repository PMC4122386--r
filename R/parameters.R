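#' @keywords internal
"_PACKAGE"

# -- condition helpers --------------------------------------------------------

stop_validation <- function(msg, field = NULL) {
  stop(structure(
    class = c("nvafce_validation_error", "error", "condition"),
    list(message = if (is.null(field)) msg else paste0(field, ": ", msg),
         call = sys.call(-1), field = field)))
}

stop_domain <- function(msg) {
  stop(structure(
    class = c("nvafce_domain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))))
}

#' Retrieve or replace a parameter by dotted path
#'
#' Parameters inside a `nvaf_parameters` object are addressed with dotted
#' paths such as `"rates.apixaban.ischemic_stroke"` or
#' `"utilities.events.stroke.mild"`.  The final path component may index a
#' named atomic vector.
#'
#' @param params a `nvaf_parameters` object (or plain nested list)
#' @param path dotted path string
#' @param value replacement value (scalar) for `set_param`
#' @return `get_param` returns the addressed value; `set_param` returns the
#'   modified parameter object.
#' @export
get_param <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  x <- params
  for (i in seq_along(keys)) {
    k <- keys[[i]]
    if (is.list(x)) {
      if (!k %in% names(x)) stop_domain(paste0("unknown parameter path: ", path))
      x <- x[[k]]
    } else if (is.atomic(x) && !is.null(names(x))) {
      if (!k %in% names(x)) stop_domain(paste0("unknown parameter path: ", path))
      x <- x[[k]]
    } else {
      stop_domain(paste0("unknown parameter path: ", path))
    }
  }
  x
}

#' @rdname get_param
#' @export
set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  rec <- function(x, keys) {
    k <- keys[[1L]]
    if (is.atomic(x)) {
      if (!k %in% names(x)) stop_domain(paste0("unknown parameter path: ", path))
      if (length(keys) > 1L) stop_domain(paste0("unknown parameter path: ", path))
      x[[k]] <- value
      return(x)
    }
    if (!k %in% names(x)) stop_domain(paste0("unknown parameter path: ", path))
    if (length(keys) == 1L) x[[k]] <- value
    else x[[k]] <- rec(x[[k]], keys[-1L])
    x
  }
  rec(params, keys)
}

# -- input-level cost preprocessing -------------------------------------------

#' Usage-weighted VKA drug cost
#'
#' The cost of vitamin-K antagonist therapy is a usage-weighted average of the
#' two coumarins prescribed in the Netherlands, acenocoumarol and
#' phenprocoumon (80%:20% in the reference parameter set).
#'
#' @param price_acenocoumarol cost per cycle of acenocoumarol (>= 0)
#' @param price_phenprocoumon cost per cycle of phenprocoumon (>= 0)
#' @param mix length-2 numeric of usage proportions
#'   (acenocoumarol, phenprocoumon) summing to 1; percentages are accepted
#'   and normalized.
#' @return weighted average cost per cycle
#' @examples
#' weighted_vka_drug_cost(0.10, 0.20, c(80, 20))  # 0.12
#' @export
weighted_vka_drug_cost <- function(price_acenocoumarol, price_phenprocoumon,
                                   mix = c(0.8, 0.2)) {
  if (price_acenocoumarol < 0 || price_phenprocoumon < 0)
    stop_domain("drug prices must be non-negative")
  if (length(mix) != 2L || any(mix < 0) || sum(mix) <= 0)
    stop_domain("mix must be two non-negative proportions")
  mix <- mix / sum(mix)
  if (abs(sum(mix) - 1) > 1e-9) stop_domain("mix must sum to 1")
  mix[[1L]] * price_acenocoumarol + mix[[2L]] * price_phenprocoumon
}

#' Inflate a cost between price years
#'
#' Scales a cost by the cumulative ratio of a consumer price index series,
#' e.g. to express historical Dutch costing-study estimates in the 2013
#' price year.
#'
#' @param cost cost in `from_year` euros
#' @param from_year,to_year integer years, both covered by `index`
#' @param index data.frame with columns `year` and `index` (index values on a
#'   common arbitrary base)
#' @return cost expressed in `to_year` euros
#' @export
inflate_cost <- function(cost, from_year, to_year, index) {
  if (from_year == to_year) return(cost)
  idx <- stats::setNames(index$index, index$year)
  for (y in c(from_year, to_year))
    if (!as.character(y) %in% names(idx))
      stop_domain(paste0("inflation index does not cover year ", y))
  cost * idx[[as.character(to_year)]] / idx[[as.character(from_year)]]
}

# -- validation ---------------------------------------------------------------

therapies <- function() c("apixaban", "vka", "asa")
ttr_events <- function() c("ischemic_stroke", "ich", "other_mb", "crnm")
all_events <- function() c(ttr_events(), "mi", "se", "other_discontinuation")

chk <- function(report, ok, field, msg) {
  if (!isTRUE(ok)) report[[length(report) + 1L]] <- list(field = field, message = msg)
  report
}

#' Validate a model parameter set
#'
#' Checks every structural invariant of the parameter schema and returns a
#' report rather than raising: an empty report means the set is valid.
#'
#' @param params a `nvaf_parameters` object
#' @return data.frame with columns `field` and `message`, zero rows if valid
#' @export
validate_parameters <- function(params) {
  r <- list()
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  co <- params$cohort
  r <- chk(r, num1(co$start_age) && co$start_age > 0, "cohort.start_age", "must be a positive number")
  r <- chk(r, num1(co$fraction_female) && co$fraction_female >= 0 && co$fraction_female <= 1,
           "cohort.fraction_female", "must be a proportion in [0,1]")
  r <- chk(r, num1(co$cohort_size) && co$cohort_size > 0, "cohort.cohort_size", "must be > 0")
  w <- co$chads2_weights
  r <- chk(r, is.numeric(w) && length(w) == 7L && all(w >= 0) && sum(w) > 0 &&
             abs(sum(w / sum(w)) - 1) <= 1e-9,
           "cohort.chads2_weights", "must be 7 non-negative weights with positive sum")
  r <- chk(r, num1(co$mean_ttr) && co$mean_ttr > 0 && co$mean_ttr < 1,
           "cohort.mean_ttr", "must lie strictly between 0 and 1")

  for (tx in therapies()) for (ev in all_events()) {
    v <- params$rates[[tx]][[ev]]
    r <- chk(r, num1(v) && v >= 0, paste("rates", tx, ev, sep = "."),
             "event rate must be a non-negative number")
  }
  st <- params$ttr_strata
  if (!is.null(st)) {
    nstr <- length(st$labels)
    r <- chk(r, length(st$breaks) == nstr + 1L && !is.unsorted(st$breaks),
             "ttr_strata.breaks", "breaks must be sorted and bracket every stratum")
    for (tx in c("apixaban", "vka")) for (ev in ttr_events()) {
      v <- st$rates[[tx]][[ev]]
      r <- chk(r, is.numeric(v) && length(v) == nstr && all(v >= 0),
               paste("ttr_strata.rates", tx, ev, sep = "."),
               "stratum rate table must cover every stratum with non-negative rates")
    }
  }

  mo <- params$modifiers
  for (ch in c("stroke", "bleed", "mi"))
    r <- chk(r, num1(mo$age_factors[[ch]]) && mo$age_factors[[ch]] > 0,
             paste0("modifiers.age_factors.", ch), "per-decade factor must be > 0")
  frac1 <- function(x) num1(x) && x >= 0 && x <= 1
  r <- chk(r, frac1(mo$hs_fraction_of_ich), "modifiers.hs_fraction_of_ich", "must be in [0,1]")
  r <- chk(r, frac1(mo$gi_fraction_of_other_mb), "modifiers.gi_fraction_of_other_mb", "must be in [0,1]")
  for (kind in c("is", "hs")) for (tx in therapies()) {
    sv <- mo$stroke_severity[[kind]][[tx]]
    fld <- paste("modifiers.stroke_severity", kind, tx, sep = ".")
    r <- chk(r, is.numeric(sv) && length(sv) == 4L && all(sv >= 0) && all(sv <= 1),
             fld, "severity split needs 4 fractions in [0,1]")
    if (is.numeric(sv) && length(sv) == 4L)
      r <- chk(r, abs(sum(sv) - 1) <= 1e-9, fld, "severity split must sum to 1")
  }
  for (ev in names(mo$case_fatality))
    r <- chk(r, frac1(mo$case_fatality[[ev]]),
             paste0("modifiers.case_fatality.", ev), "case-fatality fraction must be in [0,1]")
  for (ev in names(mo$post_bleed_stay))
    r <- chk(r, frac1(mo$post_bleed_stay[[ev]]),
             paste0("modifiers.post_bleed_stay.", ev), "stay fraction must be in [0,1]")
  for (ps in c("post_is", "post_hs")) {
    v <- mo$recurrence_annual[[ps]]
    r <- chk(r, num1(v) && v >= 0 && v < 1,
             paste0("modifiers.recurrence_annual.", ps), "annual recurrence risk must be in [0,1)")
  }
  r <- chk(r, num1(mo$trial_period_years) && mo$trial_period_years > 0,
           "modifiers.trial_period_years", "must be > 0")
  for (m in c("af", "mi", "se"))
    r <- chk(r, num1(mo$excess_mortality[[m]]) && mo$excess_mortality[[m]] >= 1,
             paste0("modifiers.excess_mortality.", m), "excess-mortality multiplier must be >= 1")
  r <- chk(r, is.numeric(mo$excess_mortality$stroke) &&
             length(mo$excess_mortality$stroke) == 3L &&
             all(mo$excess_mortality$stroke >= 1),
           "modifiers.excess_mortality.stroke", "needs 3 multipliers (mild, moderate, severe) >= 1")

  ut <- params$utilities
  util1 <- function(x) num1(x) && x >= 0 && x <= 1
  r <- chk(r, util1(ut$af_baseline), "utilities.af_baseline", "must be in [0,1]")
  r <- chk(r, is.numeric(ut$events$stroke) && length(ut$events$stroke) == 3L &&
             all(ut$events$stroke >= 0 & ut$events$stroke <= 1),
           "utilities.events.stroke", "needs 3 utilities in [0,1]")
  for (ev in c("mi", "se"))
    r <- chk(r, util1(ut$events[[ev]]), paste0("utilities.events.", ev), "must be in [0,1]")
  for (b in names(ut$bleed_decrements)) {
    bd <- ut$bleed_decrements[[b]]
    r <- chk(r, num1(bd$decrement) && bd$decrement >= 0,
             paste0("utilities.bleed_decrements.", b, ".decrement"), "must be >= 0")
    r <- chk(r, num1(bd$duration_weeks) && bd$duration_weeks > 0,
             paste0("utilities.bleed_decrements.", b, ".duration_weeks"), "must be > 0")
  }
  for (tx in therapies())
    r <- chk(r, num1(ut$treatment_decrements[[tx]]) && ut$treatment_decrements[[tx]] >= 0,
             paste0("utilities.treatment_decrements.", tx), "must be >= 0")
  r <- chk(r, ut$joint_method %in% c("multiplicative", "minimum"),
           "utilities.joint_method", "must be 'multiplicative' or 'minimum'")

  cs <- params$costs
  nonneg <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0)
  for (fld in c("routine_care_per_cycle", "inr_monitoring_per_cycle"))
    r <- chk(r, num1(cs[[fld]]) && cs[[fld]] >= 0, paste0("costs.", fld), "must be >= 0")
  for (d in names(cs$drug_per_cycle))
    r <- chk(r, num1(cs$drug_per_cycle[[d]]) && cs$drug_per_cycle[[d]] >= 0,
             paste0("costs.drug_per_cycle.", d), "must be >= 0")
  r <- chk(r, is.numeric(cs$vka_mix) && length(cs$vka_mix) == 2L && all(cs$vka_mix >= 0) &&
             abs(sum(cs$vka_mix) - 1) <= 1e-9, "costs.vka_mix", "two proportions summing to 1")
  for (grp in names(cs$acute))
    r <- chk(r, nonneg(cs$acute[[grp]]), paste0("costs.acute.", grp), "acute costs must be >= 0")
  r <- chk(r, nonneg(cs$long_term_monthly$stroke) && nonneg(cs$long_term_monthly$mi),
           "costs.long_term_monthly", "long-term costs must be >= 0")

  se <- params$settings
  r <- chk(r, num1(se$cycle_length_weeks) && se$cycle_length_weeks > 0,
           "settings.cycle_length_weeks", "must be > 0")
  for (fld in c("discount_rate_costs", "discount_rate_effects"))
    r <- chk(r, num1(se[[fld]]) && se[[fld]] >= 0, paste0("settings.", fld), "must be >= 0")
  r <- chk(r, num1(se$psa_iterations) && se$psa_iterations >= 1,
           "settings.psa_iterations", "must be >= 1")
  r <- chk(r, num1(se$max_age) && se$max_age > co$start_age,
           "settings.max_age", "must exceed the cohort starting age")

  lt <- params$life_table
  r <- chk(r, is.data.frame(lt) && all(c("age", "male", "female") %in% names(lt)) &&
             min(lt$age) <= co$start_age && max(lt$age) >= se$max_age,
           "life_table", "must cover ages from the starting age to max_age")

  r <- chk(r, !is.null(params$schema_version), "schema_version", "missing schema version")

  if (length(r) == 0L)
    return(data.frame(field = character(), message = character(),
                      stringsAsFactors = FALSE))
  data.frame(field = vapply(r, `[[`, "", "field"),
             message = vapply(r, `[[`, "", "message"),
             stringsAsFactors = FALSE)
}

#' Assemble and validate a model parameter object
#'
#' Normalizes a nested parameter list into a `nvaf_parameters` object:
#' CHADS2 weights and usage mixes given as percentages are rescaled to
#' proportions, and every schema invariant is enforced.
#'
#' @param x nested list following the configuration schema
#' @return validated object of class `nvaf_parameters`
#' @export
as_nvaf_parameters <- function(x) {
  x <- normalize_config(x)
  w <- x$cohort$chads2_weights
  if (sum(w) <= 0) stop_validation("weights must have positive sum", "cohort.chads2_weights")
  x$cohort$chads2_weights <- w / sum(w)
  if (sum(x$costs$vka_mix) > 0) x$costs$vka_mix <- x$costs$vka_mix / sum(x$costs$vka_mix)
  if (!is.null(x$cohort$chads2_reference_weights)) {
    rw <- x$cohort$chads2_reference_weights
    x$cohort$chads2_reference_weights <- rw / sum(rw)
  }
  class(x) <- "nvaf_parameters"
  rep <- validate_parameters(x)
  if (nrow(rep) > 0L)
    stop_validation(paste0(rep$field[1L], " - ", rep$message[1L],
                           if (nrow(rep) > 1L) paste0(" (and ", nrow(rep) - 1L,
                                                      " further violation(s))")))
  x
}

# coerce yaml-parsed lists back into the canonical vector/data.frame shapes
normalize_config <- function(x) {
  req <- c("cohort", "rates", "modifiers", "utilities", "costs", "settings",
           "life_table", "schema_version")
  for (k in req)
    if (is.null(x[[k]])) stop_validation("missing required key", k)
  nv <- function(v) if (is.list(v)) unlist(v) else v
  x$cohort$chads2_weights <- nv(x$cohort$chads2_weights)
  if (!is.null(x$cohort$chads2_reference_weights))
    x$cohort$chads2_reference_weights <- nv(x$cohort$chads2_reference_weights)
  if (!is.null(x$chads2_stroke_rates)) x$chads2_stroke_rates <- nv(x$chads2_stroke_rates)
  if (!is.null(x$ttr_strata)) {
    x$ttr_strata$breaks <- nv(x$ttr_strata$breaks)
    x$ttr_strata$labels <- unlist(x$ttr_strata$labels)
    for (tx in names(x$ttr_strata$rates))
      for (ev in names(x$ttr_strata$rates[[tx]]))
        x$ttr_strata$rates[[tx]][[ev]] <- nv(x$ttr_strata$rates[[tx]][[ev]])
  }
  for (kind in c("is", "hs"))
    for (tx in names(x$modifiers$stroke_severity[[kind]]))
      x$modifiers$stroke_severity[[kind]][[tx]] <- nv(x$modifiers$stroke_severity[[kind]][[tx]])
  x$modifiers$excess_mortality$stroke <- nv(x$modifiers$excess_mortality$stroke)
  x$utilities$events$stroke <- nv(x$utilities$events$stroke)
  x$costs$vka_mix <- nv(x$costs$vka_mix)
  for (grp in names(x$costs$acute)) x$costs$acute[[grp]] <- nv(x$costs$acute[[grp]])
  x$costs$long_term_monthly$stroke <- nv(x$costs$long_term_monthly$stroke)
  if (!is.data.frame(x$life_table))
    x$life_table <- data.frame(age = nv(x$life_table$age),
                               male = nv(x$life_table$male),
                               female = nv(x$life_table$female))
  if (!is.data.frame(x$costs$inflation_index) && !is.null(x$costs$inflation_index))
    x$costs$inflation_index <- data.frame(year = nv(x$costs$inflation_index$year),
                                          index = nv(x$costs$inflation_index$index))
  x$settings$wtp_thresholds <- nv(x$settings$wtp_thresholds)
  x
}

#' Read a model configuration file
#'
#' Configurations are single human-readable YAML documents carrying a
#' `schema_version` field; see `reference_parameters()` for the documented
#' schema. All invariants are enforced on load.
#'
#' @param path path to a YAML configuration file
#' @return validated `nvaf_parameters` object
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("configuration file not found: ", path))
  as_nvaf_parameters(yaml::read_yaml(path))
}

#' Write a model configuration file
#'
#' Round-trip companion to [load_model_config()].
#'
#' @param params `nvaf_parameters` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_model_config <- function(params, path) {
  yaml::write_yaml(as_config_list(params), path, precision = 12L)
  invisible(path)
}

# YAML-safe representation: data.frames become column lists and named atomic
# vectors become named lists (yaml writes unnamed sequences otherwise, which
# would lose the names on reload)
as_config_list <- function(x) {
  if (is.data.frame(x)) return(lapply(as.list(x), unname))
  if (is.list(x)) return(lapply(x, as_config_list))
  if (is.atomic(x) && !is.null(names(x)) && length(x) > 0L) return(as.list(x))
  x
}

#' @export
print.nvaf_parameters <- function(x, ...) {
  cat("<nvaf_parameters> schema", x$schema_version, "\n")
  cat(sprintf("  cohort: %d patients, age %g, %.1f%% female, mean TTR %.2f%%\n",
              as.integer(x$cohort$cohort_size), x$cohort$start_age,
              100 * x$cohort$fraction_female, 100 * x$cohort$mean_ttr))
  cat(sprintf("  cycle %g weeks, horizon to age %g, discounting %g%%/%g%% (costs/effects)\n",
              x$settings$cycle_length_weeks, x$settings$max_age,
              100 * x$settings$discount_rate_costs, 100 * x$settings$discount_rate_effects))
  cat("  therapies:", paste(therapies(), collapse = ", "), "\n")
  invisible(x)
}

#' Convert a 95% confidence interval to a standard error
#'
#' Assumes normality on the parameter's natural scale, the convention used
#' when only interval estimates are reported for sensitivity analyses.
#'
#' @param lower,upper 95% CI bounds
#' @return standard error
#' @export
ci_to_se <- function(lower, upper) {
  if (upper < lower) stop_domain("upper CI bound below lower bound")
  (upper - lower) / (2 * stats::qnorm(0.975))
}
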