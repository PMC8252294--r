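check_thrips_records <- function(events, followup_days = NULL) {
  req <- c("accession", "day", "status")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    abort(paste0("Thrips event records lack columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(events) == 0) abort("No thrips event records supplied.")
  if (any(events$day < 1)) abort("Event days must be >= 1.")
  if (!all(events$status %in% c(0, 1))) abort("`status` must be 0 or 1.")
  if (!is.null(followup_days) && any(events$day > followup_days)) {
    abort("Event days exceed the follow-up horizon.")
  }
  invisible(events)
}

#' Kaplan-Meier survival curves and median survival per accession
#'
#' Product-limit estimate of larval survival per accession. The median
#' survival time is the smallest observed day at which the estimated
#' survival drops to 0.5 or below; when the curve never reaches 0.5 within
#' follow-up, the median is undefined and reported as `NA` with a note that
#' it exceeds the horizon. By default medians sit on the daily observation
#' grid (no interpolation); `interpolate = TRUE` instead interpolates
#' linearly between the curve steps bracketing 0.5, which can give
#' half-day medians.
#'
#' @param events A data frame with columns `accession`, `day`, `status`
#'   (1 = died, 0 = censored at `day`); usually also `individual_id`.
#' @param interpolate Interpolate the median between daily steps
#'   (default `FALSE`).
#' @return An object of class `km_fit`; `tidy()` returns the stepwise
#'   curves (`accession`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`), and `$medians` / [median_survival()] the per-accession
#'   medians.
#' @export
kaplan_meier <- function(events, interpolate = FALSE) {
  check_thrips_records(events)
  sf <- survival::survfit(survival::Surv(day, status) ~ accession,
                          data = events)
  strata <- if (is.null(sf$strata)) {
    rep(as.character(events$accession[1]), length(sf$time))
  } else {
    rep(sub("^accession=", "", names(sf$strata)), sf$strata)
  }
  curves <- tibble(accession = strata, time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, n_censor = sf$n.censor,
                   survival = sf$surv)
  medians <- curves %>%
    group_by(.data$accession) %>%
    summarise(median_day = km_median(.data$time, .data$survival, interpolate),
              .groups = "drop") %>%
    mutate(note = ifelse(is.na(.data$median_day),
                         "survival never reached 0.5: median > follow-up horizon",
                         NA_character_))
  structure(list(curves = curves, medians = medians, survfit = sf,
                 interpolate = interpolate),
            class = "km_fit")
}

km_median <- function(time, surv, interpolate) {
  idx <- which(surv <= 0.5)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (!interpolate || i == 1 || surv[i] == 0.5) return(time[i])
  # linear interpolation between the last step above 0.5 and the first at/below
  t0 <- time[i - 1]; s0 <- surv[i - 1]
  t1 <- time[i]; s1 <- surv[i]
  t0 + (s0 - 0.5) / (s0 - s1) * (t1 - t0)
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> Kaplan-Meier curves for",
      dplyr::n_distinct(x$curves$accession), "accessions\n")
  print(x$medians, ...)
  invisible(x)
}

#' @rdname kaplan_meier
#' @param x A `km_fit`.
#' @param ... Unused.
#' @export
tidy.km_fit <- function(x, ...) x$curves

#' @rdname kaplan_meier
#' @export
glance.km_fit <- function(x, ...) {
  tibble(n_accessions = dplyr::n_distinct(x$curves$accession),
         n_events = sum(x$curves$n_event),
         n_censored = sum(x$curves$n_censor))
}

#' @rdname kaplan_meier
#' @export
median_survival <- function(events, interpolate = FALSE) {
  kaplan_meier(events, interpolate = interpolate)$medians
}

#' Fit the thrips Cox proportional-hazards model
#'
#' Partial-likelihood fit of larval death hazard with accession as the
#' explanatory variable and the supplied susceptible standard as reference.
#' Because survival was scored once a day the data carry heavy ties; the
#' Efron approximation is the default (`ties = "breslow"` is available).
#' An exponentiated coefficient above 1 means larvae die faster on that
#' accession than on the baseline. Accessions without a single death have
#' a divergent (non-estimable) coefficient and are flagged rather than
#' dropped.
#'
#' @param events Thrips event records as in [kaplan_meier()].
#' @param baseline_accession The susceptible reference accession.
#' @param ties Tie-handling method passed to [survival::coxph()].
#' @return An object of class `thrips_fit` supporting [tidy()] and
#'   [glance()]; `tidy()` has one row per accession with `estimate`
#'   (log hazard ratio), `exp_estimate`, `std_error`, `p_value`, `note`.
#' @seealso [classify_thrips()]
#' @export
fit_cox <- function(events, baseline_accession, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_thrips_records(events)
  if (!baseline_accession %in% events$accession) {
    abort(paste0("Baseline accession '", baseline_accession,
                 "' absent from the records."))
  }
  if (dplyr::n_distinct(events$accession) < 2) {
    abort("Need at least two accessions to fit the Cox model.")
  }
  if (sum(events$status) == 0) {
    abort("No deaths observed; the Cox model is not estimable.")
  }
  d <- as_tibble(events)
  d$accession <- stats::relevel(factor(d$accession), ref = baseline_accession)
  # divergent coefficients (zero-death accessions) are flagged below, so
  # the fitter's infinite-coefficient warning is redundant here
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(day, status) ~ accession,
                    data = d, ties = ties),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  no_deaths <- d %>%
    group_by(.data$accession) %>%
    summarise(deaths = sum(.data$status), .groups = "drop") %>%
    filter(.data$deaths == 0)
  structure(list(fit = fit, baseline = baseline_accession,
                 zero_death = as.character(no_deaths$accession),
                 accessions = sort(unique(as.character(d$accession))),
                 ties = ties),
            class = "thrips_fit")
}

#' @export
print.thrips_fit <- function(x, ...) {
  cat("<thrips_fit> Cox PH (", x$ties, " ties), baseline: ", x$baseline,
      "\n", sep = "")
  invisible(x)
}

#' @rdname fit_cox
#' @param x A `thrips_fit`.
#' @param ... Unused.
#' @export
tidy.thrips_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  rn <- rownames(sm)
  est <- tibble(
    accession = sub("^accession", "", rn),
    estimate = sm[, "coef"],
    std_error = sm[, "se(coef)"],
    p_value = sm[, "Pr(>|z|)"],
    note = NA_character_
  )
  out <- tibble(accession = x$accessions) %>%
    left_join(est, by = "accession") %>%
    mutate(
      note = case_when(
        .data$accession == x$baseline ~ "baseline",
        .data$accession %in% x$zero_death ~
          "non-estimable: no deaths observed",
        TRUE ~ .data$note
      ),
      exp_estimate = exp(.data$estimate)
    )
  out$estimate[out$accession == x$baseline] <- 0
  out$exp_estimate[out$accession == x$baseline] <- 1
  out %>%
    select("accession", "estimate", "exp_estimate", "std_error",
           "p_value", "note")
}

#' @rdname fit_cox
#' @export
glance.thrips_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = s$n, n_events = s$nevent,
         concordance = unname(s$concordance["C"]),
         likelihood_ratio_p = unname(s$logtest["pvalue"]))
}

#' Classify accessions as thrips resistant or susceptible
#'
#' An accession is resistant when its hazard ratio versus the susceptible
#' standard exceeds 1 (larvae die faster) and the Wald p-value is below
#' `alpha` (default 0.01, the stringent threshold); the baseline and
#' zero-death (non-estimable, hazard ratio below 1 by construction)
#' accessions are susceptible.
#'
#' @param fit A [fit_cox()] result.
#' @param alpha Significance level, default 0.01.
#' @return A phenotype-label tibble: `accession`, `insect`, `class`,
#'   `coefficient` (log hazard), `exp_coefficient` (hazard ratio),
#'   `p_value`, `note`.
#' @export
classify_thrips <- function(fit, alpha = 0.01) {
  stopifnot(inherits(fit, "thrips_fit"))
  tidy(fit) %>%
    mutate(
      insect = "thrips",
      class = case_when(
        .data$accession == fit$baseline ~ "susceptible",
        .data$accession %in% fit$zero_death ~ "susceptible",
        .data$exp_estimate > 1 & .data$p_value < alpha ~ "resistant",
        TRUE ~ "susceptible"
      )
    ) %>%
    select("accession", "insect", "class",
           coefficient = "estimate", exp_coefficient = "exp_estimate",
           "p_value", "note")
}
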