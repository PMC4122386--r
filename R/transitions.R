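# State space and cycle-indexed transition model.
#
# Health states: baseline AF on apixaban/VKA/ASA; a one-cycle drug-holiday
# state (anticoagulant suspended after a non-HS ICH); post-ischemic-stroke
# and post-haemorrhagic-stroke states by severity and first/recurrent flag
# (post-IS keeps the anticoagulant, post-HS is maintenance-only); absorbing
# post-SE (anticoagulant kept) and post-MI (maintenance-only) states; dead.
# Bleeding events (other ICH, other MB, CRNM) are transient: they are
# annotated on transitions and re-route therapy rather than occupying states,
# with their utility decrements and acute costs booked at the event cycle.

severity_levels <- function() c("mild", "moderate", "severe")

.nvafce_cache <- new.env(parent = emptyenv())

#' Enumerate the model state space
#'
#' @return data.frame with one row per state: `name`, `category`, `therapy`
#'   (`"none"` for maintenance-only states and dead), `severity`,
#'   `recurrent`, `alive`, and `stay_dest` (state receiving the residual
#'   probability; the drug-holiday states return to baseline).
#' @export
state_space <- function() {
  if (!is.null(.nvafce_cache$state_space)) return(.nvafce_cache$state_space)
  rows <- list()
  add <- function(name, category, therapy = "none", severity = NA_character_,
                  recurrent = FALSE, alive = TRUE, stay_dest = name) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, category = category, therapy = therapy, severity = severity,
      recurrent = recurrent, alive = alive, stay_dest = stay_dest,
      stringsAsFactors = FALSE)
  }
  for (tx in therapies()) add(paste0("base_", tx), "base", tx)
  for (tx in c("apixaban", "vka"))
    add(paste0("holiday_", tx), "holiday", tx, stay_dest = paste0("base_", tx))
  for (flag in c("first", "rec")) for (sv in severity_levels())
    for (tx in therapies())
      add(paste("pis", flag, sv, tx, sep = "_"), "post_is", tx, sv, flag == "rec")
  for (flag in c("first", "rec")) for (sv in severity_levels())
    add(paste("phs", flag, sv, sep = "_"), "post_hs", "none", sv, flag == "rec")
  for (tx in therapies()) add(paste0("pse_", tx), "post_se", tx)
  add("pmi", "post_mi")
  add("dead", "dead", alive = FALSE)
  .nvafce_cache$state_space <- do.call(rbind, rows)
  .nvafce_cache$state_space
}

#' Event annotation keys
#'
#' Keys under which per-cycle event flows are tallied (type x severity x
#' fatality x first/recurrent).
#' @return character vector
#' @export
event_keys <- function() {
  c(paste0("is_first_", c(severity_levels(), "fatal")),
    paste0("is_rec_", c(severity_levels(), "fatal")),
    paste0("hs_first_", c(severity_levels(), "fatal")),
    paste0("hs_rec_", c(severity_levels(), "fatal")),
    "se_nonfatal", "se_fatal",
    "other_ich_nonfatal", "other_ich_fatal",
    "mb_gi_nonfatal", "mb_nongi_nonfatal", "mb_fatal",
    "crnm",
    "mi_nonfatal", "mi_fatal",
    "other_disc")
}

# Long edge table: one row per (source state, cause, destination, event
# annotation) with the annual hazard at the cohort's starting age and the
# age-escalation channel it follows.
model_edges <- function(params) {
  info <- state_space()
  S <- nrow(info)
  sid <- stats::setNames(seq_len(S), info$name)
  ek <- stats::setNames(seq_along(event_keys()), event_keys())
  mo <- params$modifiers
  chfac <- chads2_rate_factor(params)

  src <- dest <- ev <- integer(0); hb <- numeric(0); ch <- character(0)
  add <- function(s, d, e, h, channel) {
    if (h <= 0) return(invisible())
    src <<- c(src, sid[[s]]); dest <<- c(dest, sid[[d]])
    ev <<- c(ev, if (is.na(e)) 0L else ek[[e]])
    hb <<- c(hb, h); ch <<- c(ch, channel)
  }

  # baseline-like states: full event exposure under a therapy's rate set
  event_edges <- function(state, rate_tx, route_tx, allow_disc) {
    r <- params$rates[[rate_tx]]
    # ischemic stroke (CHADS2-weighted), severity split of the routed therapy
    h_is <- (r$ischemic_stroke / 100) * chfac
    s_is <- mo$stroke_severity$is[[rate_tx]]
    for (j in 1:3)
      add(state, paste("pis_first", severity_levels()[j], route_tx, sep = "_"),
          paste0("is_first_", severity_levels()[j]), h_is * s_is[j], "stroke")
    add(state, "dead", "is_first_fatal", h_is * s_is[4], "stroke")
    # intracranial haemorrhage: haemorrhagic stroke vs other ICH
    h_ich <- r$ich / 100
    hs_part <- split_ich(h_ich, mo$hs_fraction_of_ich)
    s_hs <- mo$stroke_severity$hs[[rate_tx]]
    for (j in 1:3)
      add(state, paste("phs_first", severity_levels()[j], sep = "_"),
          paste0("hs_first_", severity_levels()[j]), hs_part[["hs"]] * s_hs[j], "bleed")
    add(state, "dead", "hs_first_fatal", hs_part[["hs"]] * s_hs[4], "bleed")
    h_oich <- hs_part[["other_ich"]]
    f <- mo$case_fatality$other_ich
    add(state, "dead", "other_ich_fatal", h_oich * f, "bleed")
    alloc <- post_event_therapy("other_ich", route_tx, mo)
    stay_dest <- if (isTRUE(alloc$stay$holiday)) paste0("holiday_", route_tx)
                 else paste0("base_", route_tx)
    add(state, stay_dest, "other_ich_nonfatal",
        h_oich * (1 - f) * alloc$stay$p, "bleed")
    add(state, "base_asa", "other_ich_nonfatal",
        h_oich * (1 - f) * alloc$switch_asa$p, "bleed")
    # other major bleeding, by GI location
    h_mb <- r$other_mb / 100
    f <- mo$case_fatality$other_mb
    add(state, "dead", "mb_fatal", h_mb * f, "bleed")
    alloc <- post_event_therapy("other_mb", route_tx, mo)
    gi <- mo$gi_fraction_of_other_mb
    for (loc in c("gi", "nongi")) {
      share <- if (loc == "gi") gi else 1 - gi
      eky <- paste0("mb_", loc, "_nonfatal")
      add(state, paste0("base_", route_tx), eky,
          h_mb * (1 - f) * share * alloc$stay$p, "bleed")
      add(state, "base_asa", eky,
          h_mb * (1 - f) * share * alloc$switch_asa$p, "bleed")
    }
    # clinically relevant non-major bleeding
    h_cr <- r$crnm / 100
    f <- mo$case_fatality$crnm
    if (f > 0) add(state, "dead", NA, h_cr * f, "bleed")
    alloc <- post_event_therapy("crnm", route_tx, mo)
    add(state, paste0("base_", route_tx), "crnm", h_cr * (1 - f) * alloc$stay$p, "bleed")
    add(state, "base_asa", "crnm", h_cr * (1 - f) * alloc$switch_asa$p, "bleed")
    # myocardial infarction -> maintenance-only absorbing state
    h_mi <- r$mi / 100
    f <- mo$case_fatality$mi
    add(state, "dead", "mi_fatal", h_mi * f, "mi")
    add(state, "pmi", "mi_nonfatal", h_mi * (1 - f), "mi")
    # systemic embolism -> absorbing, therapy kept
    h_se <- r$se / 100
    f <- mo$case_fatality$se
    add(state, "dead", "se_fatal", h_se * f, "fixed")
    add(state, paste0("pse_", route_tx), "se_nonfatal", h_se * (1 - f), "fixed")
    # other treatment discontinuation -> ASA
    if (allow_disc && route_tx != "asa")
      add(state, "base_asa", "other_disc", r$other_discontinuation / 100, "fixed")
  }

  mort_edge <- function(state, mult) add(state, "dead", NA, mult, "mort")

  for (tx in therapies()) {
    event_edges(paste0("base_", tx), tx, tx, allow_disc = TRUE)
    mort_edge(paste0("base_", tx), mo$excess_mortality$af)
  }
  # drug holiday: anticoagulant suspended, event exposure at ASA-level rates,
  # post-event routing keeps the suspended therapy; residual returns to base
  for (tx in c("apixaban", "vka")) {
    event_edges(paste0("holiday_", tx), "asa", tx, allow_disc = FALSE)
    mort_edge(paste0("holiday_", tx), mo$excess_mortality$af)
  }
  # post-IS: one recurrent stroke allowed, severity split of apixaban first
  # strokes; excess mortality by severity
  rec_is <- mo$recurrence_annual$post_is
  s_rec <- mo$stroke_severity$is$apixaban
  for (sv in severity_levels()) for (tx in therapies()) {
    st <- paste("pis_first", sv, tx, sep = "_")
    for (j in 1:3)
      add(st, paste("pis_rec", severity_levels()[j], tx, sep = "_"),
          paste0("is_rec_", severity_levels()[j]), rec_is * s_rec[j], "recur")
    add(st, "dead", "is_rec_fatal", rec_is * s_rec[4], "recur")
    mort_edge(st, mo$excess_mortality$stroke[[sv]])
    mort_edge(paste("pis_rec", sv, tx, sep = "_"), mo$excess_mortality$stroke[[sv]])
  }
  rec_hs <- mo$recurrence_annual$post_hs
  s_rec_hs <- mo$stroke_severity$hs$apixaban
  for (sv in severity_levels()) {
    st <- paste("phs_first", sv, sep = "_")
    for (j in 1:3)
      add(st, paste("phs_rec", severity_levels()[j], sep = "_"),
          paste0("hs_rec_", severity_levels()[j]), rec_hs * s_rec_hs[j], "recur")
    add(st, "dead", "hs_rec_fatal", rec_hs * s_rec_hs[4], "recur")
    mort_edge(st, mo$excess_mortality$stroke[[sv]])
    mort_edge(paste("phs_rec", sv, sep = "_"), mo$excess_mortality$stroke[[sv]])
  }
  for (tx in therapies()) mort_edge(paste0("pse_", tx), mo$excess_mortality$se)
  mort_edge("pmi", mo$excess_mortality$mi)

  list(info = info, src = src, dest = dest, event = ev, hbase = hb, channel = ch)
}

#' Construct a transition model from explicit matrices
#'
#' Low-level constructor used directly in validation exercises (e.g. the
#' microsimulation cross-check on small hand-made chains).  Every row of
#' every matrix must sum to 1 within 1e-12.
#'
#' @param states character vector of state names
#' @param P list of S x S transition matrices (one per distinct cycle regime)
#' @param cycle_key integer vector mapping each cycle to an element of `P`
#' @param cycle_years cycle length in years
#' @param start_state name of the state holding the cohort at cycle 0
#' @param E optional list of S x K event-flow matrices parallel to `P`
#' @param keys event key names for the columns of `E`
#' @param cycle_age,cycle_time optional per-cycle attained age / start time
#' @param arm label
#' @return object of class `nvaf_transitions`
#' @export
transition_model <- function(states, P, cycle_key, cycle_years, start_state,
                             E = NULL, keys = character(0),
                             cycle_age = NULL, cycle_time = NULL,
                             arm = "custom") {
  S <- length(states)
  for (m in P) {
    if (!all(dim(m) == c(S, S))) stop_domain("transition matrix dimension mismatch")
    if (any(m < -1e-15) || any(m > 1 + 1e-15))
      stop_domain("transition probabilities must lie in [0,1]")
    if (any(abs(rowSums(m) - 1) > 1e-12))
      stop_domain("transition rows must sum to 1 within 1e-12")
  }
  if (is.null(E)) E <- lapply(P, function(m) matrix(0, S, 0))
  structure(list(states = states, P = P, E = E, event_keys = keys,
                 cycle_key = as.integer(cycle_key),
                 cycle_age = cycle_age, cycle_time = cycle_time,
                 cycle_years = cycle_years, start_state = start_state,
                 arm = arm, info = NULL),
            class = "nvaf_transitions")
}

#' Build the full transition model for one treatment arm
#'
#' Converts annual rates to cycle probabilities, applies the CHADS2 case-mix
#' factor, per-decade age escalation (stepwise at whole-year boundaries),
#' severity/fatality splits, post-event therapy routing, recurrence, and
#' mortality layering (trial-based other-cause mortality during the trial
#' period, sex-weighted life-table mortality thereafter, scaled by
#' state-specific excess multipliers).
#'
#' @param params validated `nvaf_parameters`
#' @param arm initial therapy, `"apixaban"` or `"vka"` (or `"asa"`)
#' @param edges precomputed edge table from an identical parameter set
#'   (internal reuse between arms; the table is arm-invariant)
#' @return `nvaf_transitions` object spanning the lifetime horizon
#' @export
build_transition_model <- function(params, arm = c("apixaban", "vka", "asa"),
                                   edges = NULL) {
  arm <- match.arg(arm)
  se <- params$settings
  cyc_years <- se$cycle_length_weeks / se$weeks_per_year
  start_age <- params$cohort$start_age
  n_cycles <- ceiling((se$max_age - start_age) / cyc_years)
  t0 <- (seq_len(n_cycles) - 1L) * cyc_years
  age <- start_age + floor(t0 + 1e-9)
  in_trial <- t0 < params$modifiers$trial_period_years

  eg <- if (is.null(edges)) model_edges(params) else edges
  info <- eg$info
  S <- nrow(info)
  sid <- stats::setNames(seq_len(S), info$name)
  K <- length(event_keys())

  # sex-weighted life-table other-cause rate per 100 py at each age
  lt <- params$life_table
  pf <- params$cohort$fraction_female
  lt_rate <- function(a) {
    i <- match(a, lt$age)
    if (any(is.na(i))) stop_domain("life table does not cover the model horizon")
    (1 - pf) * lt$male[i] + pf * lt$female[i]
  }
  trial_rate <- params$modifiers$trial_noncv_mortality[[if (arm == "asa") "vka" else arm]]

  af <- params$modifiers$age_factors
  keydf <- unique(data.frame(age = age, trial = in_trial))
  cycle_key <- match(interaction(age, in_trial, drop = TRUE),
                     interaction(keydf$age, keydf$trial, drop = TRUE))

  # precomputed index structures for fast accumulation
  is_mort <- eg$channel == "mort"
  pgrp <- (eg$dest - 1L) * S + eg$src
  pu <- sort(unique(pgrp)); pmap <- match(pgrp, pu)
  has_ev <- eg$event > 0L
  egrp <- (eg$event[has_ev] - 1L) * S + eg$src[has_ev]
  eu <- sort(unique(egrp)); emap <- match(egrp, eu)
  stay_idx <- cbind(seq_len(S), sid[info$stay_dest])
  t_years <- cyc_years

  Plist <- vector("list", nrow(keydf)); Elist <- vector("list", nrow(keydf))
  for (k in seq_len(nrow(keydf))) {
    a <- keydf$age[k]
    dec <- (a - start_age) / 10
    fac <- c(stroke = af$stroke^dec, bleed = af$bleed^dec, mi = af$mi^dec,
             recur = 1, fixed = 1, mort = 1)
    h <- eg$hbase * fac[eg$channel]
    h[is_mort] <- eg$hbase[is_mort] *
      (if (keydf$trial[k]) trial_rate else lt_rate(a)) / 100
    Hs <- numeric(S)
    hs_sum <- rowsum(h, eg$src)
    Hs[as.integer(rownames(hs_sum))] <- hs_sum[, 1L]
    pany <- ifelse(Hs > 0, 1 - exp(-Hs * t_years), 0)
    flow <- ifelse(Hs[eg$src] > 0, h / Hs[eg$src] * pany[eg$src], 0)

    P <- matrix(0, S, S, dimnames = list(info$name, info$name))
    ps <- rowsum(flow, pmap)
    P[pu] <- ps[, 1L]
    out_total <- numeric(S)
    ot <- rowsum(flow, eg$src)
    out_total[as.integer(rownames(ot))] <- ot[, 1L]
    P[stay_idx] <- P[stay_idx] + (1 - out_total)

    E <- matrix(0, S, K, dimnames = list(info$name, event_keys()))
    es <- rowsum(flow[has_ev], emap)
    E[eu] <- es[, 1L]
    Plist[[k]] <- P; Elist[[k]] <- E
  }

  m <- transition_model(info$name, Plist, cycle_key, cyc_years,
                        paste0("base_", arm), E = Elist, keys = event_keys(),
                        cycle_age = age, cycle_time = t0, arm = arm)
  m$info <- info
  m
}

#' @export
print.nvaf_transitions <- function(x, ...) {
  cat(sprintf("<nvaf_transitions> arm %s: %d states, %d cycles (%d regimes), cycle %.4f y\n",
              x$arm, length(x$states), length(x$cycle_key), length(x$P),
              x$cycle_years))
  invisible(x)
}

#' Export a transition model as a long-format table
#'
#' One row per (from, to, cycle regime) with the attained age, arm and
#' transition probability; suitable for audit as CSV.
#'
#' @param model `nvaf_transitions` object
#' @param path optional CSV path; when given the table is also written there
#' @return data.frame (invisibly when `path` is given)
#' @export
export_transition_model <- function(model, path = NULL) {
  out <- list()
  for (k in seq_along(model$P)) {
    P <- model$P[[k]]
    nz <- which(P != 0, arr.ind = TRUE)
    cyc <- which(model$cycle_key == k)[1L]
    out[[k]] <- data.frame(
      state_from = model$states[nz[, 1L]],
      state_to = model$states[nz[, 2L]],
      regime = k,
      age = if (!is.null(model$cycle_age)) model$cycle_age[cyc] else NA,
      arm = model$arm,
      probability = P[nz],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
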