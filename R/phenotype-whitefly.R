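#' Per-accession mean whitefly survival
#'
#' Cage survival fractions are first averaged over the clip cages of each
#' plant, then plant means are averaged per accession; the standard error
#' is taken across plants (the biological replicate).
#'
#' @param records A data frame of clip-cage counts with columns `accession`,
#'   `plant_id`, `cage_id`, `n_alive`, `n_dead` (each cage must contain at
#'   least one insect).
#' @return A tibble with `accession`, `mean_survival`, `se` (NA for a single
#'   plant), `n_plants`.
#' @export
#' @examples
#' rec <- tibble::tibble(accession = "a", plant_id = "p1",
#'                       cage_id = c("c1", "c2"),
#'                       n_alive = c(10, 12), n_dead = c(5, 3))
#' mean_survival(rec) # (10/15 + 12/15) / 2 = 0.733
mean_survival <- function(records) {
  check_whitefly_records(records)
  records %>%
    mutate(frac = .data$n_alive / (.data$n_alive + .data$n_dead)) %>%
    group_by(.data$accession, .data$plant_id) %>%
    summarise(plant_mean = mean(.data$frac), .groups = "drop") %>%
    group_by(.data$accession) %>%
    summarise(mean_survival = mean(.data$plant_mean),
              se = sd(.data$plant_mean) / sqrt(dplyr::n()),
              n_plants = dplyr::n(), .groups = "drop")
}

check_whitefly_records <- function(records) {
  req <- c("accession", "plant_id", "cage_id", "n_alive", "n_dead")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    abort(paste0("Whitefly records lack columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0) abort("No whitefly records supplied.")
  if (any(records$n_alive < 0) || any(records$n_dead < 0)) {
    abort("Counts must be non-negative.")
  }
  if (any(records$n_alive + records$n_dead == 0)) {
    abort("Every cage must contain at least one insect.")
  }
  invisible(records)
}

#' Fit the whitefly survival GLM
#'
#' Fits a binomial GLM (logit link) on plant-level aggregated alive/dead
#' counts with accession as a fixed effect and the supplied sensitive
#' standard as the reference (intercept) level. Accessions with 0% overall
#' survival are excluded from the fit before estimation (their logit
#' coefficient is not finite) and flagged; they are labelled resistant
#' downstream.
#'
#' @param records Clip-cage counts as in [mean_survival()].
#' @param baseline_accession The susceptible reference accession (must be
#'   present in `records`).
#' @return An object of class `whitefly_fit` supporting [tidy()] and
#'   [glance()]; `tidy()` gives one row per accession with the logit-scale
#'   `estimate` versus baseline, `std_error`, `p_value` (Wald) and a `note`
#'   for the baseline, exclusions and non-estimable coefficients.
#' @seealso [classify_whitefly()]
#' @export
fit_whitefly_glm <- function(records, baseline_accession) {
  check_whitefly_records(records)
  if (!baseline_accession %in% records$accession) {
    abort(paste0("Baseline accession '", baseline_accession,
                 "' absent from the records."))
  }
  plant <- records %>%
    group_by(.data$accession, .data$plant_id) %>%
    summarise(alive = sum(.data$n_alive), dead = sum(.data$n_dead),
              .groups = "drop")

  totals <- plant %>%
    group_by(.data$accession) %>%
    summarise(alive = sum(.data$alive), .groups = "drop")
  excluded <- totals$accession[totals$alive == 0]
  if (baseline_accession %in% excluded) {
    abort("The baseline accession has zero survival; choose another standard.")
  }
  fit_data <- plant %>% filter(!.data$accession %in% excluded)
  if (dplyr::n_distinct(fit_data$accession) < 2) {
    abort("Need at least two accessions (after exclusions) to fit the GLM.")
  }
  fit_data$accession <- stats::relevel(factor(fit_data$accession),
                                       ref = baseline_accession)
  fit <- stats::glm(cbind(alive, dead) ~ accession,
                    family = stats::binomial(), data = fit_data)
  structure(list(fit = fit,
                 baseline = baseline_accession,
                 excluded = excluded,
                 accessions = sort(unique(records$accession))),
            class = "whitefly_fit")
}

#' @export
print.whitefly_fit <- function(x, ...) {
  cat("<whitefly_fit> binomial GLM (logit), baseline:", x$baseline, "\n")
  cat("  accessions:", length(x$accessions),
      " excluded (zero survival):",
      if (length(x$excluded)) paste(x$excluded, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' @rdname fit_whitefly_glm
#' @param x A `whitefly_fit`.
#' @param ... Unused.
#' @export
tidy.whitefly_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  rn <- rownames(sm)
  acc_rows <- grepl("^accession", rn)
  est <- tibble(
    accession = sub("^accession", "", rn[acc_rows]),
    estimate = sm[acc_rows, "Estimate"],
    std_error = sm[acc_rows, "Std. Error"],
    p_value = sm[acc_rows, "Pr(>|z|)"],
    note = NA_character_
  ) %>%
    # Wald inference collapses under quasi-separation (e.g. 100% survival):
    # the estimate diverges and the SE explodes. Flag, do not drop.
    mutate(note = ifelse(.data$std_error > 20,
                         "non-estimable: quasi-separation", .data$note))
  out <- tibble(accession = x$accessions) %>%
    left_join(est, by = "accession") %>%
    mutate(note = case_when(
      .data$accession == x$baseline ~ "baseline",
      .data$accession %in% x$excluded ~ "excluded from GLM: zero survival",
      TRUE ~ .data$note
    ))
  out$estimate[out$accession == x$baseline] <- 0
  out
}

#' @rdname fit_whitefly_glm
#' @export
glance.whitefly_fit <- function(x, ...) {
  tibble(null_deviance = x$fit$null.deviance,
         deviance = x$fit$deviance,
         df_residual = x$fit$df.residual,
         aic = x$fit$aic,
         n_accessions = length(x$accessions),
         n_excluded = length(x$excluded))
}

#' Classify accessions as whitefly resistant or susceptible
#'
#' An accession is resistant when its GLM coefficient versus the sensitive
#' standard is negative (lower survival) and Wald-significant at `alpha`;
#' accessions excluded for 0% survival are resistant by construction; the
#' baseline is susceptible. The direction requirement matters: a
#' significantly *higher* survival than baseline is not resistance.
#'
#' @param fit A [fit_whitefly_glm()] result.
#' @param alpha Significance level, default 0.05.
#' @return A phenotype-label tibble: `accession`, `insect`, `class`,
#'   `coefficient` (logit scale), `exp_coefficient` (odds ratio), `p_value`,
#'   `note`.
#' @export
classify_whitefly <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "whitefly_fit"))
  tidy(fit) %>%
    mutate(
      insect = "whitefly",
      class = case_when(
        .data$accession %in% fit$excluded ~ "resistant",
        .data$accession == fit$baseline ~ "susceptible",
        !is.na(.data$note) & .data$note == "non-estimable: quasi-separation" ~
          "susceptible",
        .data$estimate < 0 & .data$p_value < alpha ~ "resistant",
        TRUE ~ "susceptible"
      ),
      exp_coefficient = exp(.data$estimate)
    ) %>%
    select("accession", "insect", "class",
           coefficient = "estimate", "exp_coefficient",
           p_value = "p_value", "note")
}
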