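#' Acylsugar nomenclature and CHO stoichiometry
#'
#' Acylsugars are glucose (G) or sucrose (S) cores esterified with short and
#' medium branched acyl chains, labelled `S{k}:{N}` / `G{k}:{N}` where `k`
#' is the number of esterified acyl groups and `N` the total number of acyl
#' carbon atoms; structural isomers get a hyphenated suffix ("S3:21-2").
#' Assuming saturated, non-hydroxylated acyl chains, the label fixes the
#' molecular formula exactly: esterifying `k` saturated acids carrying `N`
#' carbons onto the core (sucrose C12H22O11, glucose C6H12O6) adds `N`
#' carbons, `2N - 2k` hydrogens and `k` oxygens, and the double-bond
#' equivalent, DBE = (2C + 2 - H)/2, equals the core ring count (2 for
#' sucrose, 1 for glucose) plus one per ester carbonyl.
#'
#' `parse_acylsugar()` parses label strings; `label_to_formula()` maps a
#' label to its CHO formula; `formula_to_label()` inverts the mapping,
#' rejecting formulas that match neither backbone exactly (unsaturated or
#' hydroxylated chains are rejected, never guessed).
#'
#' @name acylsugar
NULL

backbone_table <- function() {
  tibble(backbone = c("S", "G"),
         c = c(12L, 6L), h = c(22L, 12L), o = c(11L, 6L),
         rings = c(2L, 1L))
}

#' @rdname acylsugar
#' @param label Character vector of labels such as `"S3:15"` or `"G2:10-1"`.
#' @return `parse_acylsugar()`: a tibble with columns `label`, `backbone`,
#'   `n_chains` (k), `acyl_carbons` (N), `isomer` (NA when unsuffixed).
#' @export
#' @examples
#' parse_acylsugar(c("S3:15", "G2:10-1"))
#' label_to_formula("S3:15")
#' formula_to_label(27, 46, 14)
parse_acylsugar <- function(label) {
  m <- regmatches(label, regexec("^([SG])([0-9]+):([0-9]+)(?:-([0-9]+))?$", label))
  bad <- lengths(m) == 0
  if (any(bad)) {
    abort(paste0("Not a valid acylsugar label: ",
                 paste(label[bad], collapse = ", ")))
  }
  out <- tibble(
    label = label,
    backbone = vapply(m, `[`, "", 2),
    n_chains = as.integer(vapply(m, `[`, "", 3)),
    acyl_carbons = as.integer(vapply(m, `[`, "", 4)),
    isomer = suppressWarnings(as.integer(vapply(m, `[`, "", 5)))
  )
  ok <- (out$n_chains == 0 & out$acyl_carbons == 0) |
    (out$n_chains > 0 & out$acyl_carbons >= 2 * out$n_chains)
  if (any(!ok)) {
    abort(paste0("Invalid chain arithmetic (need N >= 2k, shortest chain is acetyl): ",
                 paste(label[!ok], collapse = ", ")))
  }
  out
}

#' @rdname acylsugar
#' @return `label_to_formula()`: a tibble with columns `label`, `n_c`,
#'   `n_h`, `n_o`, `dbe`.
#' @export
label_to_formula <- function(label) {
  p <- parse_acylsugar(label)
  bb <- backbone_table()
  i <- match(p$backbone, bb$backbone)
  tibble(
    label = p$label,
    n_c = bb$c[i] + p$acyl_carbons,
    n_h = bb$h[i] + 2L * p$acyl_carbons - 2L * p$n_chains,
    n_o = bb$o[i] + p$n_chains,
    dbe = bb$rings[i] + p$n_chains
  )
}

#' @rdname acylsugar
#' @param n_c,n_h,n_o Element counts of a CHO formula (vectorised).
#' @param dbe_range Accepted DBE window for candidate acylsugars
#'   (annotation constraint used when reconstructing parent ions).
#' @return `formula_to_label()`: a tibble with columns `n_c`, `n_h`, `n_o`,
#'   `dbe`, `label` (NA on rejection), `backbone`, `n_chains`,
#'   `acyl_carbons`, and `reason` explaining any rejection.
#' @export
formula_to_label <- function(n_c, n_h, n_o, dbe_range = c(1, 10)) {
  len <- max(length(n_c), length(n_h), length(n_o))
  n_c <- rep_len(as.integer(n_c), len)
  n_h <- rep_len(as.integer(n_h), len)
  n_o <- rep_len(as.integer(n_o), len)
  dbe2 <- 2L * n_c + 2L - n_h
  bb <- backbone_table()

  one <- function(c_, h_, o_, dbe2_) {
    if (dbe2_ %% 2L != 0L || dbe2_ < 0L) {
      return(list(label = NA_character_, backbone = NA_character_,
                  n_chains = NA_integer_, acyl_carbons = NA_integer_,
                  dbe = dbe2_ / 2, reason = "DBE is not a non-negative integer"))
    }
    dbe <- dbe2_ %/% 2L
    if (dbe < dbe_range[1] || dbe > dbe_range[2]) {
      return(list(label = NA_character_, backbone = NA_character_,
                  n_chains = NA_integer_, acyl_carbons = NA_integer_,
                  dbe = dbe, reason = sprintf("DBE %d outside [%d, %d]",
                                              dbe, dbe_range[1], dbe_range[2])))
    }
    for (j in seq_len(nrow(bb))) {
      k <- dbe - bb$rings[j]
      N <- c_ - bb$c[j]
      if (k < 0L || N < 0L) next
      if (k == 0L && N != 0L) next
      if (k > 0L && N < 2L * k) next
      h_exp <- bb$h[j] + 2L * N - 2L * k
      o_exp <- bb$o[j] + k
      if (h_ == h_exp && o_ == o_exp) {
        return(list(label = sprintf("%s%d:%d", bb$backbone[j], k, N),
                    backbone = bb$backbone[j], n_chains = k,
                    acyl_carbons = N, dbe = dbe, reason = NA_character_))
      }
    }
    list(label = NA_character_, backbone = NA_character_,
         n_chains = NA_integer_, acyl_carbons = NA_integer_, dbe = dbe,
         reason = "not a saturated acylsugar: no S/G backbone fits the CHO counts")
  }

  res <- purrr::pmap(list(n_c, n_h, n_o, dbe2), one)
  tibble(
    n_c = n_c, n_h = n_h, n_o = n_o,
    dbe = purrr::map_dbl(res, "dbe"),
    label = purrr::map_chr(res, "label"),
    backbone = purrr::map_chr(res, "backbone"),
    n_chains = purrr::map_int(res, "n_chains"),
    acyl_carbons = purrr::map_int(res, "acyl_carbons"),
    reason = purrr::map_chr(res, "reason")
  )
}

# Monoisotopic masses (u) of the elements and adducts handled here.
atomic_mass <- c(C = 12.000000, H = 1.007825, O = 15.994915,
                 Na = 22.989770, K = 38.963707)

#' Monoisotopic mass of a CHO formula
#'
#' @param n_c,n_h,n_o Element counts (vectorised).
#' @return Neutral monoisotopic mass in u.
#' @export
#' @examples
#' monoisotopic_mass(15, 24, 0) # alpha-humulene, 204.188
monoisotopic_mass <- function(n_c, n_h, n_o = 0) {
  n_c * atomic_mass[["C"]] + n_h * atomic_mass[["H"]] + n_o * atomic_mass[["O"]]
}

#' m/z of a common ESI adduct of a CHO molecule
#'
#' Monoisotopic adduct masses are added to the neutral monoisotopic mass;
#' the electron mass (~0.00055 u) is neglected, which is far below the
#' reporting precision used here.
#'
#' @param n_c,n_h,n_o Element counts of the neutral molecule, or the first
#'   argument may be an acylsugar label string (then `n_h`/`n_o` are ignored).
#' @param adduct One of `"[M+H]+"`, `"[M+Na]+"`, `"[M+K]+"`, `"[M+HCOO]-"`.
#' @return m/z value(s).
#' @export
#' @examples
#' adduct_mz("S3:15", adduct = "[M+Na]+") # 617.28
adduct_mz <- function(n_c, n_h = NULL, n_o = NULL,
                      adduct = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+HCOO]-")) {
  adduct <- match.arg(adduct)
  if (is.character(n_c)) {
    f <- label_to_formula(n_c)
    n_c <- f$n_c; n_h <- f$n_h; n_o <- f$n_o
  }
  m <- monoisotopic_mass(n_c, n_h, n_o)
  shift <- switch(adduct,
    "[M+H]+" = atomic_mass[["H"]],
    "[M+Na]+" = atomic_mass[["Na"]],
    "[M+K]+" = atomic_mass[["K"]],
    "[M+HCOO]-" = atomic_mass[["C"]] + atomic_mass[["H"]] +
      2 * atomic_mass[["O"]]
  )
  m + shift
}

#' Check an acylsugar label against a reported parent-ion m/z
#'
#' Compares the m/z implied by a label under the saturated-chain
#' stoichiometry with a reported (printed or measured) parent-ion m/z for
#' a given adduct. Reported masses sometimes disagree with what the
#' nomenclature implies — e.g. an S3:21 parent ion reported at m/z 715
#' as the sodium adduct, where saturated S3:21 (C33H58O14) gives 701.4.
#' Such disagreements are surfaced, never silently corrected on either
#' side: the label may describe an unsaturated/hydroxylated variant, or
#' the reported mass may be wrong.
#'
#' @param label Acylsugar label string(s).
#' @param reported_mz Reported parent-ion m/z, same length.
#' @param adduct Adduct assumed for the reported ion.
#' @param tol Absolute m/z agreement tolerance (default 0.5, i.e.
#'   nominal-mass agreement).
#' @return A tibble with `label`, `reported_mz`, `expected_mz` (from the
#'   saturated stoichiometry), `delta` and `consistent`.
#' @export
#' @examples
#' annotation_consistency(c("S3:15", "S3:21"), c(617, 715))
annotation_consistency <- function(label, reported_mz,
                                   adduct = "[M+Na]+", tol = 0.5) {
  f <- label_to_formula(label)
  expected <- adduct_mz(f$n_c, f$n_h, f$n_o, adduct)
  tibble(label = f$label,
         reported_mz = reported_mz,
         expected_mz = expected,
         delta = reported_mz - expected,
         consistent = abs(reported_mz - expected) <= tol)
}
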