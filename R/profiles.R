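#' Define a strain kinetic profile
#'
#' A strain profile holds, per substrate, the four redox rate constants
#' (plus an optional reductase deactivation rate), an oxygen-dependence
#' flag for its oxidation activity, and the wet biomass density it is
#' resuspended at. Substrates without an entry are inert for that strain.
#'
#' @param strain_id Strain label.
#' @param activities Named list, one entry per substrate: a list with any of
#'   `k_red_R`, `k_red_S`, `k_ox_S`, `k_ox_R` (1/h, >= 0) and `red_decay`
#'   (1/h, default 0).
#' @param oxygen_dependent_oxidation If `TRUE` (default) the strain's
#'   oxidation rates vanish under anaerobic incubation (oxidase activity);
#'   `FALSE` models an oxygen-independent dehydrogenase back-reaction.
#' @param biomass Wet cell weight density, g/L.
#' @param cross_inhibition Optional list `list(substrate=, by=, factor=)`:
#'   the strain's reduction of `substrate` is multiplied by `factor` when
#'   `by` is co-incubated (models substrate-mixture interference).
#' @param pool_inhibition Optional list `list(substrates=, factor=)`: the
#'   strain suppresses its pool-mates' (and its own) reduction of the named
#'   substrates by `factor` (models an excreted inhibitor).
#' @return A `strain_profile` object.
#' @export
strain_profile <- function(strain_id, activities = list(),
                           oxygen_dependent_oxidation = TRUE,
                           biomass = 100, cross_inhibition = NULL,
                           pool_inhibition = NULL) {
  stopifnot(is.character(strain_id), length(strain_id) == 1L)
  activities <- lapply(activities, function(a) {
    a <- utils::modifyList(
      list(k_red_R = 0, k_red_S = 0, k_ox_S = 0, k_ox_R = 0, red_decay = 0),
      a)
    if (any(unlist(a) < 0)) stop("rates must be >= 0", call. = FALSE)
    a
  })
  structure(list(strain_id = strain_id,
                 activities = activities,
                 oxygen_dependent_oxidation = isTRUE(oxygen_dependent_oxidation),
                 biomass = biomass,
                 cross_inhibition = cross_inhibition,
                 pool_inhibition = pool_inhibition),
            class = "strain_profile")
}

#' @export
print.strain_profile <- function(x, ...) {
  cat("strain", x$strain_id,
      if (length(x$activities) == 0L) "(inactive)" else "", "\n")
  for (s in names(x$activities)) {
    a <- x$activities[[s]]
    cat(sprintf("  %s: k_red_R=%.3g k_red_S=%.3g k_ox_S=%.3g k_ox_R=%.3g%s\n",
                s, a$k_red_R, a$k_red_S, a$k_ox_S, a$k_ox_R,
                if (a$red_decay > 0) sprintf(" decay=%.3g", a$red_decay) else ""))
  }
  invisible(x)
}

#' Prior ranges for random strain-profile generation
#'
#' Defaults emulate a small whole-cell library in which most strains show
#' little or no activity toward any one substrate: 60% of strains are fully
#' inactive, active strains draw a total reduction rate uniformly from
#' 0.02-0.35 per h (4 h conversions of roughly 8-75% for a single strain)
#' with a uniform enantioselectivity, and 15% of active strains carry an
#' additional (S)-selective, oxygen-dependent oxidation activity of
#' 0.1-0.5 per h.
#'
#' @param k_red Range (low, high) of the total reduction rate, 1/h.
#' @param k_ox Range of the (S)-oxidation rate for oxidizer strains, 1/h.
#' @param selectivity Range of the reduction enantioselectivity, as the
#'   signed ee of the alcohol the strain would produce ((R) positive).
#' @param inactive_fraction Fraction of strains with no activity at all.
#' @param oxidizer_fraction Fraction of active strains that also oxidize.
#' @return A `profile_priors` list.
#' @export
profile_priors <- function(k_red = c(0.02, 0.35), k_ox = c(0.1, 0.5),
                           selectivity = c(-1, 1),
                           inactive_fraction = 0.6,
                           oxidizer_fraction = 0.15) {
  chk_range <- function(r, lo_ok = 0) {
    length(r) == 2L && all(is.finite(r)) && r[1L] <= r[2L] && r[1L] >= lo_ok
  }
  if (!chk_range(k_red) || !chk_range(k_ox) ||
      !(chk_range(selectivity, -1) && selectivity[2L] <= 1)) {
    stop("invalid prior ranges: need low <= high and admissible bounds",
         call. = FALSE)
  }
  if (inactive_fraction < 0 || inactive_fraction > 1 ||
      oxidizer_fraction < 0 || oxidizer_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(k_red = k_red, k_ox = k_ox, selectivity = selectivity,
                 inactive_fraction = inactive_fraction,
                 oxidizer_fraction = oxidizer_fraction),
            class = "profile_priors")
}

#' Draw random strain profiles
#'
#' Reproducible under `seed`; see [profile_priors()] for the generative
#' model.
#'
#' @param n Number of strains.
#' @param substrates Substrate labels each strain gets (independent) rates
#'   for.
#' @param priors A `profile_priors`.
#' @param seed Optional integer seed.
#' @param ids Optional strain labels.
#' @return List of `n` [strain_profile()] objects.
#' @export
generate_strain_profiles <- function(n, substrates = "ketone",
                                     priors = profile_priors(),
                                     seed = NULL, ids = NULL) {
  stopifnot(n >= 0, inherits(priors, "profile_priors"))
  if (n == 0L) return(list())
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  stopifnot(length(ids) == n)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      if (stats::runif(1) < priors$inactive_fraction) {
        return(strain_profile(ids[i]))
      }
      acts <- lapply(substrates, function(sub) {
        k_tot <- stats::runif(1, priors$k_red[1L], priors$k_red[2L])
        sel <- stats::runif(1, priors$selectivity[1L], priors$selectivity[2L])
        a <- list(k_red_R = k_tot * (1 + sel) / 2,
                  k_red_S = k_tot * (1 - sel) / 2)
        if (stats::runif(1) < priors$oxidizer_fraction) {
          a$k_ox_S <- stats::runif(1, priors$k_ox[1L], priors$k_ox[2L])
        }
        a
      })
      names(acts) <- substrates
      strain_profile(ids[i], acts)
    })
  })
}
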