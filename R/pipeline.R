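#' Run the full synthetic pipeline
#'
#' End-to-end orchestration on simulated data: generate a metabolite table
#' and both bioassays, phenotype the accessions (binomial GLM for whitefly,
#' Cox model for thrips), run the permutation-null random-forest selection
#' against the chosen insect's labels, and assemble the report tables.
#' Useful both as a worked example and for validating the whole chain
#' against the generator's ground truth.
#'
#' @param config A [sim_config()].
#' @param selection A [selection_config()]; defaults to the standard
#'   procedure with the same seed as `config`.
#' @param insect Which phenotype drives the selection (default whitefly).
#' @return A list with `truth`, `feature_table`, `phenotypes` (label
#'   tibble), `selection` (an `rf_selection`), `report`, and `recovery`
#'   (tibble comparing selected features with the planted ground truth).
#' @export
run_pipeline <- function(config = sim_config(),
                         selection = NULL,
                         insect = c("whitefly", "thrips")) {
  insect <- match.arg(insect)
  if (is.null(selection)) selection <- selection_config(seed = config$seed)
  sim <- simulate_feature_table(config)
  baseline <- baseline_accession(config)

  labels <- if (insect == "whitefly") {
    wf <- simulate_whitefly_assay(config)
    classify_whitefly(fit_whitefly_glm(wf, baseline))
  } else {
    th <- simulate_thrips_assay(config)
    classify_thrips(fit_cox(th, baseline))
  }

  sel <- rf_select(sim$table, labels, selection)
  rep <- render_reports(sel, sim$table, labels)

  selected_feat <- tidy(sel)$feature[tidy(sel)$selected]
  planted_feat <- sim$truth$planted_features
  all_feat <- union(planted_feat, selected_feat)
  recovery <- tibble(
    feature = all_feat,
    planted = all_feat %in% planted_feat,
    selected = all_feat %in% selected_feat
  )
  list(truth = sim$truth, feature_table = sim$table, phenotypes = labels,
       selection = sel, report = rep, recovery = recovery)
}
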