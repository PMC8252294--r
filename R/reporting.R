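#' Relative survival scores
#'
#' Rescales per-accession survival summaries (mean whitefly survival or
#' median thrips survival time) so the highest value is 100%; the result is
#' invariant to multiplying all inputs by a positive constant.
#'
#' @param data A data frame with one row per accession.
#' @param score Column holding the survival summary (tidy-eval).
#' @return `data` with an added `relative_survival` column in percent.
#' @export
#' @examples
#' relative_survival(tibble::tibble(accession = c("a", "b", "c"),
#'                                  score = c(0.22, 0.44, 0.88)), score)
relative_survival <- function(data, score) {
  v <- dplyr::pull(data, {{ score }})
  if (!length(v)) abort("No accessions supplied.")
  if (any(v < 0, na.rm = TRUE)) abort("Survival scores must be non-negative.")
  mx <- max(v, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    abort("All survival scores are zero; relative survival is undefined.")
  }
  dplyr::mutate(data, relative_survival = {{ score }} / mx * 100)
}

#' Aggregate trichome densities per accession and trichome type
#'
#' Leaf-disc densities are averaged per plant, leaflet surface and trichome
#' type; the surfaces are then combined according to the insect's access
#' (whiteflies move freely between both leaf surfaces, so abaxial and
#' adaxial means are averaged; thrips larvae were confined to the adaxial
#' surface, so only that surface is used); finally plant values are
#' averaged per accession.
#'
#' @param records A data frame with columns `accession`, `plant_id`,
#'   `leaf_disc_id`, `surface` (`"abaxial"`/`"adaxial"`), `trichome_type`,
#'   `density` (trichomes per mm^2, non-negative).
#' @param insect `"whitefly"` or `"thrips"`.
#' @return A tibble `accession` x `trichome_type` with mean `density`.
#' @export
aggregate_density <- function(records, insect = c("whitefly", "thrips")) {
  insect <- match.arg(insect)
  req <- c("accession", "plant_id", "leaf_disc_id", "surface",
           "trichome_type", "density")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    abort(paste0("Trichome records lack columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(records$density < 0)) abort("Densities must be non-negative.")
  if (!all(records$surface %in% c("abaxial", "adaxial"))) {
    abort("`surface` must be 'abaxial' or 'adaxial'.")
  }
  disc <- records %>%
    group_by(.data$accession, .data$plant_id, .data$surface,
             .data$trichome_type) %>%
    summarise(density = mean(.data$density), .groups = "drop")
  if (insect == "whitefly") {
    both <- disc %>%
      group_by(.data$accession, .data$plant_id, .data$trichome_type) %>%
      summarise(n_surf = dplyr::n_distinct(.data$surface),
                density = mean(.data$density), .groups = "drop")
    if (any(both$n_surf < 2)) {
      abort("Whitefly aggregation needs both leaf surfaces for every plant.")
    }
    plant <- both
  } else {
    plant <- disc %>% filter(.data$surface == "adaxial")
    if (nrow(plant) == 0) abort("No adaxial records for thrips aggregation.")
  }
  plant %>%
    group_by(.data$accession, .data$trichome_type) %>%
    summarise(density = mean(.data$density), .groups = "drop")
}

#' Simple linear regression of survival on trichome density
#'
#' Ordinary least squares with the coefficient of determination and the
#' slope t-test p-value, the summary reported for density-survival
#' relationships.
#'
#' @param data A data frame.
#' @param x,y Predictor and response columns (tidy-eval).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
#' @examples
#' linear_fit(tibble::tibble(d = 1:5, s = c(2.1, 3.9, 6.2, 8.0, 9.9)), d, s)
linear_fit <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) abort("Need at least three complete observations.")
  if (sd(xv) == 0) abort("Predictor has zero variance.")
  fit <- lm(yv ~ xv)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients["xv", "Pr(>|t|)"],
         n = length(xv))
}

#' Complete-linkage clustering of metabolite features
#'
#' Clusters features (rows of the transposed accession-mean matrix) by
#' complete-linkage agglomeration. The default distance is Euclidean on
#' log10(x + 1)-transformed abundances, which tames the orders-of-magnitude
#' spread typical of ion counts; raw-scale Euclidean and correlation
#' distances are selectable. Features are ordered alphabetically before
#' clustering so equal-distance merges resolve deterministically.
#'
#' @param features A `feature_table`, wide accession-mean tibble with an
#'   `accession` column, or matrix (accessions x features).
#' @param transform `"log10"` (default, log10(x + 1)) or `"raw"`.
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson r).
#' @return An object of class `feature_clustering` wrapping the
#'   [stats::hclust()] tree; `tidy()` gives the leaf ordering, `$heights`
#'   the (non-decreasing) merge heights.
#' @export
cluster_features <- function(features, transform = c("log10", "raw"),
                             distance = c("euclidean", "correlation")) {
  transform <- match.arg(transform)
  distance <- match.arg(distance)
  if (inherits(features, "feature_table")) features <- features$wide
  if (!is.matrix(features)) {
    features <- as.data.frame(features)
    rn <- features$accession
    features <- as.matrix(features[, setdiff(names(features), "accession"),
                                   drop = FALSE])
    rownames(features) <- rn
  }
  if (ncol(features) < 2) abort("Need at least two features to cluster.")
  m <- t(features[, order(colnames(features)), drop = FALSE])
  if (transform == "log10") m <- log10(m + 1)
  d <- switch(distance,
    euclidean = dist(m),
    correlation = as.dist(1 - stats::cor(t(m)))
  )
  hc <- hclust(d, method = "complete")
  structure(list(hclust = hc,
                 order = rownames(m)[hc$order],
                 heights = hc$height,
                 transform = transform, distance = distance),
            class = "feature_clustering")
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat("<feature_clustering> complete linkage on ", x$distance, " distance (",
      x$transform, " scale), ", length(x$order), " features\n", sep = "")
  invisible(x)
}

#' @rdname cluster_features
#' @param x A `feature_clustering`.
#' @param ... Unused.
#' @export
tidy.feature_clustering <- function(x, ...) {
  tibble(feature = x$order, position = seq_along(x$order))
}

#' Summaries backing the selection report
#'
#' Produces the machine-readable tables behind the standard figures: a
#' per-selected-feature abundance panel with log10-scaled means and
#' delta-method standard errors (`se(log10 mean) = se / (mean ln 10)`), and
#' a long heatmap table of log10(x + 1) accession-mean abundances in
#' cluster order.
#'
#' @param selection An [rf_select()] result.
#' @param ft The `feature_table` the selection was run on.
#' @param labels Optional phenotype-label tibble (`accession`, `class`)
#'   carried into the abundance panel.
#' @return A list with `selected` (tibble of selected features and
#'   p-values), `abundance_panel` (accession x selected-feature log10 means
#'   with SEs) and `heatmap` (long clustered abundance table). With no
#'   selected features, `selected` is empty and `abundance_panel` is
#'   `NULL`; a message notes that no significant features were found.
#' @export
render_reports <- function(selection, ft, labels = NULL) {
  stopifnot(inherits(selection, "rf_selection"),
            inherits(ft, "feature_table"))
  res <- tidy(selection)
  sel <- filter(res, .data$selected)
  clus <- cluster_features(ft)
  heat <- ft$wide %>%
    tidyr::pivot_longer(-"accession", names_to = "feature",
                        values_to = "abundance") %>%
    mutate(log10_abundance = log10(.data$abundance + 1),
           feature = factor(.data$feature, levels = clus$order)) %>%
    arrange(.data$feature, .data$accession)

  if (nrow(sel) == 0) {
    inform("No significant features at the configured threshold.")
    panel <- NULL
  } else {
    panel <- ft$long %>%
      filter(.data$feature_id %in% sel$feature) %>%
      group_by(.data$accession, feature = .data$feature_id) %>%
      summarise(mean_abundance = mean(.data$abundance),
                se_abundance = sd(.data$abundance) / sqrt(dplyr::n()),
                .groups = "drop") %>%
      mutate(log10_mean = log10(.data$mean_abundance),
             # delta method on the log10 scale; undefined at zero means
             log10_se = ifelse(.data$mean_abundance > 0,
                               .data$se_abundance /
                                 (.data$mean_abundance * log(10)),
                               NA_real_))
    if (!is.null(labels)) {
      panel <- left_join(panel,
                         distinct(as_tibble(labels), .data$accession,
                                  .data$class),
                         by = "accession")
    }
  }
  list(selected = sel, abundance_panel = panel, heatmap = heat)
}
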