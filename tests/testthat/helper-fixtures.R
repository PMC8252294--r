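# Shared in-code fixtures for the test suite.

# One cage per plant holding aggregated alive/dead counts per accession.
aggregated_whitefly <- function(counts) {
  # counts: named list accession -> c(alive, dead)
  purrr::imap_dfr(counts, function(ad, acc) {
    tibble::tibble(accession = acc, plant_id = paste0(acc, "_p1"),
                   cage_id = paste0(acc, "_c1"),
                   n_alive = ad[1], n_dead = ad[2])
  })
}

# Thrips event records from lists with $day and $status per named accession.
thrips_events <- function(...) {
  groups <- list(...)
  purrr::imap_dfr(groups, function(g, acc) {
    tibble::tibble(accession = acc,
                   individual_id = paste0(acc, "_i", seq_along(g$day)),
                   day = g$day, status = g$status)
  })
}

# A small wide table with a perfectly class-separating feature plus noise.
perfect_feature_data <- function(n_per_class = 10, n_noise = 19, seed = 11) {
  set.seed(seed)
  n <- 2 * n_per_class
  cls <- rep(c("resistant", "susceptible"), each = n_per_class)
  x <- matrix(rlnorm(n * n_noise, 5, 1), n, n_noise,
              dimnames = list(NULL, sprintf("noise%02d", seq_len(n_noise))))
  wide <- tibble::as_tibble(x)
  wide$accession <- sprintf("a%02d", seq_len(n))
  wide$sig <- as.numeric(cls == "resistant")
  wide <- wide[, c("accession", "sig", sprintf("noise%02d", seq_len(n_noise)))]
  labels <- tibble::tibble(accession = wide$accession, class = cls)
  list(features = wide, labels = labels)
}
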