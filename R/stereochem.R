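#' Enantiomeric excess from enantiomer amounts
#'
#' Standard definition `ee = (R - S) / (R + S)`, signed with (R) positive,
#' the convention used throughout this package.
#'
#' @param R,S Non-negative amounts of the (R)- and (S)-enantiomer.
#' @return Signed ee fraction in [-1, 1].
#' @examples
#' ee_from_amounts(0.778, 0.072)  # ~ +0.83
#' @export
ee_from_amounts <- function(R, S) {
  stopifnot(all(R >= 0), all(S >= 0))
  tot <- R + S
  if (any(tot == 0)) {
    stop("ee undefined: R + S must be > 0", call. = FALSE)
  }
  (R - S) / tot
}

#' Enantiomer fractions from total alcohol and ee
#'
#' Inverts [ee_from_amounts()]: `R = total*(1+ee)/2`, `S = total*(1-ee)/2`.
#' The degenerate `total_alcohol = 0` case returns zero fractions with ee
#' flagged undefined.
#'
#' @param total_alcohol Alcohol as a fraction of initial material, in [0,1].
#' @param ee Signed ee fraction, |ee| <= 1.
#' @return An `enantiomer_split`: list with `total_alcohol`, `ee`,
#'   `R_fraction`, `S_fraction`, `ee_defined`.
#' @examples
#' split_from_ee(0.85, 0.83)  # R 0.77775, S 0.07225
#' @export
split_from_ee <- function(total_alcohol, ee) {
  stopifnot(length(total_alcohol) == 1L, length(ee) == 1L)
  if (total_alcohol < 0 || total_alcohol > 1) {
    stop("total_alcohol must lie in [0, 1]", call. = FALSE)
  }
  if (abs(ee) > 1) stop("|ee| must be <= 1", call. = FALSE)
  structure(
    list(total_alcohol = total_alcohol,
         ee = if (total_alcohol > 0) ee else NA_real_,
         R_fraction = total_alcohol * (1 + ee) / 2,
         S_fraction = total_alcohol * (1 - ee) / 2,
         ee_defined = total_alcohol > 0),
    class = "enantiomer_split")
}

#' @export
print.enantiomer_split <- function(x, ...) {
  cat(sprintf("alcohol %.4g (R %.4g / S %.4g), ee %s\n",
              x$total_alcohol, x$R_fraction, x$S_fraction,
              if (x$ee_defined) sprintf("%+.3f", x$ee) else "undefined"))
  invisible(x)
}

#' Upper bound on (R)-alcohol yield under oxidation alone
#'
#' If the only available reaction is oxidation of alcohol to ketone (no
#' reduction), the (R)-alcohol pool can never grow: the attainable
#' (R)-alcohol yield from an alcohol of enantiomeric excess `initial_ee` is
#' at most its initial share, `(1 + initial_ee)/2`. From a racemate that
#' bound is 50%; an observed (R) yield above it proves that ketone
#' re-reduction must be operating alongside the enantioselective oxidation
#' (tandem stereoinversion), which is the inference this bound exists for.
#'
#' @param initial_ee Signed ee of the starting alcohol, |ee| <= 1.
#' @return Maximum (R)-alcohol fraction of the initial material.
#' @export
max_R_yield_oxidation_only <- function(initial_ee) {
  stopifnot(all(abs(initial_ee) <= 1))
  (1 + initial_ee) / 2
}

#' Infer whether re-reduction accompanied an enantioselective oxidation
#'
#' Compares an observed enantiomer split against the oxidation-only bound
#' of [max_R_yield_oxidation_only()]. Strict excess is required: an
#' observation exactly on the bound does not support a re-reduction claim.
#'
#' @param observed An `enantiomer_split` (e.g. from [split_from_ee()]).
#' @param initial_ee Signed ee of the starting alcohol.
#' @return List with `reduction_present` (logical) and `margin`
#'   (observed R fraction minus the bound).
#' @examples
#' obs <- split_from_ee(0.85, 0.83)        # 15% ketone, 83% ee alcohol
#' infer_reduction_present(obs, 0)         # TRUE, margin ~ 0.278
#' @export
infer_reduction_present <- function(observed, initial_ee = 0) {
  stopifnot(inherits(observed, "enantiomer_split"))
  bound <- max_R_yield_oxidation_only(initial_ee)
  margin <- observed$R_fraction - bound
  list(reduction_present = margin > 0, margin = margin)
}

#' Enantioselectivity ratio E of a kinetic resolution
#'
#' For an irreversible kinetic resolution in which the two enantiomers are
#' consumed with first-order rates `k_fast`/`k_slow`, the selectivity
#' `E = k_fast/k_slow` follows from conversion `c` and substrate ee:
#' `E = log((1-c)(1-ee_s)) / log((1-c)(1+ee_s))`. Values beyond `cap`
#' (numerically indistinguishable from perfect resolution) are returned as
#' the cap. The relation assumes no back-reaction; when the reverse
#' (reduction) step is active the returned value carries a caveat
#' attribute.
#'
#' @param conversion Fraction converted, strictly in (0, 1).
#' @param ee_substrate Residual-substrate ee fraction in [0, 1).
#' @param cap Sentinel returned for effectively infinite selectivity.
#' @param back_reaction Set `TRUE` to mark the estimate as biased by an
#'   active reverse reaction.
#' @return E >= 1 (numeric), with attribute `caveat` when flagged.
#' @export
kinetic_resolution_E <- function(conversion, ee_substrate, cap = 1000,
                                 back_reaction = FALSE) {
  if (conversion <= 0 || conversion >= 1) {
    stop("E undefined at conversion 0 or 1", call. = FALSE)
  }
  if (ee_substrate < 0 || ee_substrate > 1) {
    stop("ee_substrate must lie in [0, 1]", call. = FALSE)
  }
  num <- log((1 - conversion) * (1 - ee_substrate))
  den <- log((1 - conversion) * (1 + ee_substrate))
  E <- if (den >= 0 || !is.finite(num)) cap else min(num / den, cap)
  if (E < 1) E <- 1  # numerical guard; selectivity is >= 1 by construction
  if (back_reaction) {
    attr(E, "caveat") <-
      "reverse reaction active: apparent E underestimates true selectivity"
  }
  E
}
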