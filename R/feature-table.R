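#' Build a normalised feature table from replicate-level measurements
#'
#' Assembles long replicate-level measurements into a `feature_table`:
#' declared co-eluting features are summed into a single merged feature
#' (e.g. a beta-phellandrene/D-limonene peak that cannot be separated),
#' absences are zero-filled so every accession x replicate carries every
#' feature, and an accession-mean wide view is computed by averaging
#' abundances across biological replicates (the form consumed by the
#' random-forest selection).
#'
#' @param measurements A data frame with columns `accession`, `replicate`,
#'   `feature_id`, `abundance` (non-negative). Additional columns (e.g. a
#'   class label) are carried through the long view. Duplicate
#'   (accession, replicate, feature_id) rows are an error.
#' @param merge_rules Optional named list; each element gives the feature
#'   ids to be summed into one feature named after the element, e.g.
#'   `list("b-phellandrene/D-limonene" = c("b-phellandrene", "D-limonene"))`.
#' @param metadata Optional per-feature metadata tibble with a `feature_id`
#'   column (class, annotation label, m/z, KI, ...).
#'
#' @return An object of class `feature_table`: a list with
#'   \describe{
#'     \item{long}{zero-filled replicate-level tibble,}
#'     \item{wide}{accession-mean tibble, one row per accession, one numeric
#'       column per feature,}
#'     \item{metadata}{the (possibly merged) feature metadata or `NULL`.}
#'   }
#' @export
#' @examples
#' m <- tibble::tibble(accession = "a1", replicate = rep(1:2, each = 2),
#'                     feature_id = rep(c("x", "y"), 2),
#'                     abundance = c(3, 4, 5, 6))
#' ft <- build_feature_table(m, merge_rules = list(xy = c("x", "y")))
#' ft$wide
build_feature_table <- function(measurements, merge_rules = NULL,
                                metadata = NULL) {
  req <- c("accession", "replicate", "feature_id", "abundance")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols)) {
    abort(paste0("`measurements` lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  m <- as_tibble(measurements)
  if (any(m$abundance < 0, na.rm = TRUE)) {
    abort("Abundances must be non-negative.")
  }
  dup <- m %>%
    dplyr::count(.data$accession, .data$replicate, .data$feature_id) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("Duplicate (accession, replicate, feature) rows, e.g. ",
                 dup$accession[1], "/", dup$replicate[1], "/",
                 dup$feature_id[1]))
  }

  if (!is.null(merge_rules)) {
    if (is.null(names(merge_rules)) || any(names(merge_rules) == "")) {
      abort("`merge_rules` must be a fully named list.")
    }
    map <- setNames(rep(names(merge_rules), lengths(merge_rules)),
                    unlist(merge_rules))
    m <- m %>%
      mutate(feature_id = dplyr::coalesce(unname(map[.data$feature_id]),
                                          .data$feature_id)) %>%
      group_by(.data$accession, .data$replicate, .data$feature_id) %>%
      summarise(abundance = sum(.data$abundance), .groups = "drop")
    if (!is.null(metadata)) {
      metadata <- metadata %>%
        mutate(feature_id = dplyr::coalesce(unname(map[.data$feature_id]),
                                            .data$feature_id)) %>%
        distinct(.data$feature_id, .keep_all = TRUE)
    }
  }

  extra <- m %>%
    select(-"replicate", -"feature_id", -"abundance") %>%
    distinct(.data$accession, .keep_all = TRUE)

  long <- m %>%
    select("accession", "replicate", "feature_id", "abundance") %>%
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("accession"), !!rlang::sym("replicate")),
      feature_id = unique(m$feature_id),
      fill = list(abundance = 0)
    ) %>%
    left_join(extra, by = "accession")

  wide <- long %>%
    group_by(.data$accession, .data$feature_id) %>%
    summarise(abundance = mean(.data$abundance), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "feature_id", values_from = "abundance") %>%
    arrange(.data$accession)

  structure(list(long = long, wide = wide, metadata = metadata),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$wide), " accessions x ",
      ncol(x$wide) - 1L, " features; ",
      dplyr::n_distinct(x$long$replicate), " replicate levels\n", sep = "")
  zero_frac <- mean(x$long$abundance == 0)
  cat(sprintf("  zero entries: %.1f%%\n", 100 * zero_frac))
  invisible(x)
}

#' Accession-mean abundance matrix of a feature table
#'
#' @param ft A `feature_table`.
#' @return A numeric matrix (accessions x features) with accession row names.
#' @export
feature_matrix <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  m <- as.matrix(ft$wide[, -1, drop = FALSE])
  rownames(m) <- ft$wide$accession
  m
}

#' Normalise a raw peak area
#'
#' Standard GC/LC-MS area normalisation: the raw area is divided by the
#' internal-standard area, scaled by the sample dilution factor and divided
#' by the fresh-leaf weight. Whether the dilution factor multiplies
#' (default) or divides is configurable because conventions differ between
#' labs.
#'
#' @param raw_area Raw integrated peak area (non-negative, vectorised).
#' @param internal_standard_area Internal-standard peak area (> 0).
#' @param dilution_factor Dilution factor (> 0), default 1.
#' @param fresh_weight Fresh tissue weight in grams (> 0), default 1.
#' @param dilution_action `"multiply"` (default) or `"divide"`.
#' @return Normalised abundance, same length as `raw_area`.
#' @export
#' @examples
#' normalize_abundance(2000, 500, dilution_factor = 2, fresh_weight = 0.1)
normalize_abundance <- function(raw_area, internal_standard_area,
                                dilution_factor = 1, fresh_weight = 1,
                                dilution_action = c("multiply", "divide")) {
  dilution_action <- match.arg(dilution_action)
  if (any(internal_standard_area <= 0)) {
    abort("`internal_standard_area` must be positive.")
  }
  if (any(fresh_weight <= 0)) abort("`fresh_weight` must be positive.")
  if (any(dilution_factor <= 0)) abort("`dilution_factor` must be positive.")
  if (any(raw_area < 0)) abort("`raw_area` must be non-negative.")
  d <- if (dilution_action == "multiply") dilution_factor else 1 / dilution_factor
  (raw_area / internal_standard_area) * d / fresh_weight
}
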