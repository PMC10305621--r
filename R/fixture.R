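#' Synthetic two-library screening study fixture
#'
#' Reconstructs the canonical screening scenario end to end: two 12-strain,
#' 4-batch, pool-size-5 libraries (batches A-D and E-H) tested on three
#' two-ketone mixtures, with ground-truth kinetic profiles chosen so the
#' batch-level readouts reproduce the study's decoding situations:
#'
#' * a fast aliphatic-ketone reducer exclusive to batch D (unique decode),
#' * two aromatic-ketone reducers sharing signature \{A,D\} (two-candidate
#'   decode, resolved by individual confirmation),
#' * a strain exclusive to batch B suspected of oxidising the aromatic
#'   product alcohols (or, alternatively, of inhibiting their formation),
#' * a fast 3-octanone reducer in batch E (unique decode at 4 h),
#' * an oxygen-dependent (S)-selective oxidizer with signature \{E,F\}
#'   pooled with fast acetophenone reducers, producing the non-monotone
#'   product curve (alcohol high at 4 h, low at 24 h) that the anomaly
#'   flagger must catch, with its signature-mate inactive (two-candidate
#'   tandem decode),
#' * a batch-B 3-octanone reducer whose activity is partially inhibited by
#'   co-incubated propiophenone (control/assay divergence).
#'
#' The batch memberships are a synthetic reconstruction: they satisfy every
#' membership constraint the study reports (exclusivities, shared
#' signatures, 8 strains in two batches and 4 in one per library) without
#' claiming to be the original table. The same memberships are shipped as
#' `inst/extdata/design_clm1_synthetic.csv` / `_clm2_`.
#'
#' @param batch_b_mode `"oxidation"` (default): the batch-B-exclusive
#'   strain oxidises the (S)-alcohols of the aromatic ketones.
#'   `"inhibition"`: it instead suppresses its pool-mates' reduction of
#'   those ketones. The study left the two hypotheses open; both
#'   configurations give low batch-B aromatic conversions.
#' @return A `clm_study_fixture`: list with `designs` (two `pool_design`s),
#'   `profiles` (named lists of [strain_profile()]s per library),
#'   `mixtures` (three substrate pairs), `channels` (which mixtures each
#'   library is incubated with), `substrates` (all five), and `truth`
#'   (ground-truth strain labels).
#' @export
make_study_fixture <- function(batch_b_mode = c("oxidation", "inhibition")) {
  batch_b_mode <- match.arg(batch_b_mode)

  clm1 <- design_from_memberships(
    list(s01 = "D",             # fast aliphatic reducer, exclusive to D
         s02 = c("A", "D"),     # aromatic reducer 1
         s03 = c("A", "D"),     # aromatic reducer 2 (same signature)
         s04 = "B",             # suspected aromatic-alcohol oxidizer
         s05 = c("A", "B"),
         s06 = c("A", "C"),
         s07 = c("A", "B"),
         s08 = c("B", "C"),
         s09 = "B",             # 3-octanone reducer, propiophenone-inhibited
         s10 = c("C", "D"),
         s11 = c("C", "D"),
         s12 = "C"),
    batch_ids = c("A", "B", "C", "D"), pool_size = 5L)

  clm2 <- design_from_memberships(
    list(t01 = "E",             # fast 3-octanone + acetophenone reducer
         t02 = c("E", "F"),     # inactive signature-mate of t03
         t03 = c("E", "F"),     # oxygen-dependent (S)-oxidizer
         t04 = c("E", "G"),
         t05 = c("E", "H"),
         t06 = c("F", "G"),
         t07 = c("F", "H"),
         t08 = "F",             # fast acetophenone reducer in F
         t09 = c("G", "H"),
         t10 = c("G", "H"),
         t11 = "G",
         t12 = "H"),
    batch_ids = c("E", "F", "G", "H"), pool_size = 5L)

  aromatic_ox <- if (batch_b_mode == "oxidation") {
    list(propiophenone = list(k_ox_S = 0.3),
         acetonaphthone = list(k_ox_S = 0.3))
  } else {
    list()
  }
  s04_inhib <- if (batch_b_mode == "inhibition") {
    list(substrates = c("propiophenone", "acetonaphthone"), factor = 0.1)
  } else {
    NULL
  }
  fast_acetophenone_red <- list(k_red_R = 0.05, k_red_S = 0.70,
                                red_decay = 0.30)

  p1 <- list(
    strain_profile("s01", list(
      `2-octanone` = list(k_red_R = 0.12),
      `3-octanone` = list(k_red_R = 0.30))),
    strain_profile("s02", list(
      propiophenone = list(k_red_S = 0.20),
      acetonaphthone = list(k_red_S = 0.15),
      acetophenone = list(k_red_S = 0.054, k_red_R = 0.0025))),
    strain_profile("s03", list(
      propiophenone = list(k_red_S = 0.12),
      acetonaphthone = list(k_red_S = 0.10))),
    strain_profile("s04", aromatic_ox, pool_inhibition = s04_inhib),
    strain_profile("s05", list(`2-octanone` = list(k_red_R = 0.002))),
    strain_profile("s06", list(`2-octanone` = list(k_red_R = 0.001),
                               propiophenone = list(k_red_S = 0.003))),
    strain_profile("s07", list(`3-octanone` = list(k_red_S = 0.004))),
    strain_profile("s08"),
    strain_profile("s09", list(`3-octanone` = list(k_red_S = 0.096)),
                   cross_inhibition = list(substrate = "3-octanone",
                                           by = "propiophenone",
                                           factor = 0.27)),
    strain_profile("s10"),
    strain_profile("s11"),
    strain_profile("s12"))

  p2 <- list(
    strain_profile("t01", list(
      `3-octanone` = list(k_red_R = 0.474),
      acetophenone = fast_acetophenone_red)),
    strain_profile("t02"),
    strain_profile("t03", list(
      acetophenone = list(k_red_R = 0.01, k_red_S = 0.04, k_ox_S = 0.40)),
      oxygen_dependent_oxidation = TRUE),
    strain_profile("t04", list(`3-octanone` = list(k_red_S = 0.003))),
    strain_profile("t05", list(acetophenone = list(k_red_S = 0.004))),
    strain_profile("t06", list(`3-octanone` = list(k_red_S = 0.002))),
    strain_profile("t07"),
    strain_profile("t08", list(acetophenone = fast_acetophenone_red)),
    strain_profile("t09"),
    strain_profile("t10"),
    strain_profile("t11"),
    strain_profile("t12"))

  structure(
    list(designs = list(clm1 = clm1, clm2 = clm2),
         profiles = list(clm1 = p1, clm2 = p2),
         mixtures = list(
           mixture1 = c("2-octanone", "acetonaphthone"),
           mixture2 = c("3-octanone", "propiophenone"),
           mixture3 = c("3-octanone", "acetophenone")),
         channels = list(clm1 = c("mixture1", "mixture2"),
                         clm2 = "mixture3"),
         substrates = c("2-octanone", "3-octanone", "acetonaphthone",
                        "propiophenone", "acetophenone"),
         batch_b_mode = batch_b_mode,
         truth = list(
           fast_aliphatic_reducer = "s01",
           aromatic_reducers = c("s02", "s03"),
           suspected_oxidizer_B = "s04",
           inhibited_reducer_B = "s09",
           fast_reducer_E = "t01",
           tandem_oxidizer_EF = "t03",
           tandem_candidates_EF = c("t02", "t03"))),
    class = "clm_study_fixture")
}

#' @export
print.clm_study_fixture <- function(x, ...) {
  cat("Synthetic screening-study fixture (mode:", x$batch_b_mode, ")\n")
  cat("  library 1: batches", paste(x$designs$clm1$batch_ids, collapse = ""),
      "x mixtures", paste(x$channels$clm1, collapse = ", "), "\n")
  cat("  library 2: batches", paste(x$designs$clm2$batch_ids, collapse = ""),
      "x", x$channels$clm2, "\n")
  cat("  substrates:", paste(x$substrates, collapse = ", "), "\n")
  invisible(x)
}
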