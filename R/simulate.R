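# Integrate a pooled incubation: one rate-term set per pool member, each
# with its own reductase-deactivation rate. Parallel catalysts add.
integrate_pool <- function(terms, y0 = c(K = 1, R = 0, S = 0),
                           times = c(4, 24)) {
  if (is.unsorted(times) || any(times < 0)) {
    stop("times must be sorted and >= 0", call. = FALSE)
  }
  if (nrow(terms) == 0L ||
      all(terms[c("k_red_R", "k_red_S", "k_ox_S", "k_ox_R")] == 0)) {
    return(data.frame(t = times,
                      K = rep(y0[["K"]], length(times)),
                      R = rep(y0[["R"]], length(times)),
                      S = rep(y0[["S"]], length(times))))
  }
  rhs <- function(t, y, p) {
    g <- exp(-terms$red_decay * t)
    kR <- sum(terms$k_red_R * g)
    kS <- sum(terms$k_red_S * g)
    koS <- sum(terms$k_ox_S)
    koR <- sum(terms$k_ox_R)
    list(c(-(kR + kS) * y[1L] + koS * y[3L] + koR * y[2L],
           kR * y[1L] - koR * y[2L],
           kS * y[1L] - koS * y[3L]))
  }
  t_solve <- unique(c(0, times))
  sol <- deSolve::lsoda(unname(y0[c("K", "R", "S")]), t_solve, rhs,
                        parms = NULL, atol = 1e-9, rtol = 1e-8)
  sol <- sol[match(times, t_solve), , drop = FALSE]
  data.frame(t = times, K = pmax(sol[, 2L], 0), R = pmax(sol[, 3L], 0),
             S = pmax(sol[, 4L], 0))
}

# Collect effective rate terms of a pool for one substrate.
pool_terms <- function(members, substrate, aeration, oxygen_factor = 1,
                       co_substrates = character()) {
  # pool-level inhibition emitted by any member (excreted-inhibitor model)
  pool_red_fac <- 1
  for (m in members) {
    pi_ <- m$pool_inhibition
    if (!is.null(pi_) && substrate %in% pi_$substrates) {
      pool_red_fac <- pool_red_fac * pi_$factor
    }
  }
  rows <- lapply(members, function(m) {
    a <- m$activities[[substrate]]
    if (is.null(a)) return(NULL)
    red_fac <- pool_red_fac
    ci <- m$cross_inhibition
    if (!is.null(ci) && identical(ci$substrate, substrate) &&
        ci$by %in% co_substrates) {
      red_fac <- ci$factor
    }
    ox_fac <- oxygen_factor
    if (aeration == "anaerobic" && m$oxygen_dependent_oxidation) ox_fac <- 0
    data.frame(k_red_R = a$k_red_R * red_fac,
               k_red_S = a$k_red_S * red_fac,
               k_ox_S = a$k_ox_S * ox_fac,
               k_ox_R = a$k_ox_R * ox_fac,
               red_decay = a$red_decay)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    data.frame(k_red_R = numeric(0), k_red_S = numeric(0),
               k_ox_S = numeric(0), k_ox_R = numeric(0),
               red_decay = numeric(0))
  } else {
    do.call(rbind, rows)
  }
}

#' Simulate GC readouts of one incubation
#'
#' Integrates the pooled redox kinetics of `members` acting on one
#' substrate (parallel first-order catalysts: member rates add), then
#' reports, at each sampling time, the conversion and the alcohol ee the
#' way a GC trace would. Multiplicative Gaussian noise (sd `noise_sd`) is
#' applied to the conversion and the result clipped to [0, 1]; an empty
#' pool is valid and yields zero conversion.
#'
#' Under anaerobic incubation the oxidation rates of every member flagged
#' `oxygen_dependent_oxidation` are zero; `oxygen_factor` scales the
#' surviving oxidation rates (see [oxygen_factor_from_biomass()]).
#'
#' @param members List of [strain_profile()] objects (possibly empty).
#' @param substrate Substrate label (selects each member's rate set).
#' @param times Sorted sampling times, hours.
#' @param aeration `"aerobic"` or `"anaerobic"`.
#' @param noise_sd Multiplicative noise sd on conversion (0 = noiseless).
#' @param seed Optional integer seed for the noise draws.
#' @param y0 Initial state; the default is pure ketone. Use
#'   `c(K=0, R=0.5, S=0.5)` for a racemic-alcohol incubation, in which case
#'   conversion is the fraction of alcohol oxidised.
#' @param label Value for the `batch_or_strain` column.
#' @param mode `"pooled"`, `"control"` or `"individual"`.
#' @param oxygen_factor Multiplier in [0,1] on aerobic oxidation rates.
#' @param co_substrates Other substrates present in the incubation
#'   (activates any matching cross-inhibition of a member).
#' @return Data frame with columns `batch_or_strain`, `substrate`,
#'   `time_h`, `conversion`, `alcohol_ee` (`NA` when no alcohol is
#'   present), `aeration`, `mode`.
#' @examples
#' s <- strain_profile("s1", list(ket = list(k_red_R = 0.1)))
#' simulate_assay(list(s), "ket", times = c(4, 24), noise_sd = 0)
#' @export
simulate_assay <- function(members, substrate, times = c(4, 24),
                           aeration = c("aerobic", "anaerobic"),
                           noise_sd = 0.03, seed = NULL,
                           y0 = c(K = 1, R = 0, S = 0),
                           label = "pool", mode = "pooled",
                           oxygen_factor = 1,
                           co_substrates = character()) {
  aeration <- match.arg(aeration)
  stopifnot(all(y0 >= 0), noise_sd >= 0)
  terms <- pool_terms(members, substrate, aeration, oxygen_factor,
                      co_substrates)
  tr <- integrate_pool(terms, y0 = y0, times = times)
  alc <- tr$R + tr$S
  ee <- ifelse(alc > 1e-12, (tr$R - tr$S) / alc, NA_real_)
  conv <- if (y0[["K"]] > 0) {
    (y0[["K"]] - tr$K) / y0[["K"]]
  } else if (sum(y0) > 0) {
    tr$K / sum(y0)
  } else {
    rep(0, nrow(tr))
  }
  conv <- pmin(pmax(conv, 0), 1)
  if (noise_sd > 0) {
    conv <- with_seed(seed, {
      conv * (1 + stats::rnorm(length(conv), 0, noise_sd))
    })
    conv <- pmin(pmax(conv, 0), 1)
  }
  data.frame(batch_or_strain = label, substrate = substrate,
             time_h = tr$t, conversion = conv, alcohol_ee = ee,
             aeration = aeration, mode = mode, row.names = NULL)
}

#' Simulate all pooled assays and controls of one library
#'
#' For every batch of `design` and every substrate mixture, produces the
#' assay rows (all mixture substrates co-incubated, cross-inhibitions
#' active) and the control rows (each substrate incubated alone with the
#' same batch), at every sampling time.
#'
#' @param design A `pool_design`.
#' @param profiles List of [strain_profile()]s covering the design's
#'   strain ids.
#' @param mixtures Named list of character vectors of substrate labels.
#' @param times Sampling times, hours.
#' @param noise_sd Multiplicative conversion noise sd.
#' @param seed Optional integer seed.
#' @param aeration Incubation aeration.
#' @return Tidy readout data frame (see [simulate_assay()] for columns).
#' @export
simulate_library <- function(design, profiles, mixtures,
                             times = c(4, 24), noise_sd = 0.03,
                             seed = NULL, aeration = "aerobic") {
  stopifnot(inherits(design, "pool_design"))
  prof_ids <- vapply(profiles, `[[`, character(1), "strain_id")
  if (!all(design$strain_ids %in% prof_ids)) {
    stop("profiles missing for strains: ",
         paste(setdiff(design$strain_ids, prof_ids), collapse = ", "),
         call. = FALSE)
  }
  names(profiles) <- prof_ids
  with_seed(seed, {
    out <- list()
    for (b in design$batch_ids) {
      members <- profiles[design$strain_ids[design$incidence[, b] == 1L]]
      for (mix in names(mixtures)) {
        subs <- mixtures[[mix]]
        for (sub in subs) {
          out[[length(out) + 1L]] <- simulate_assay(
            members, sub, times = times, aeration = aeration,
            noise_sd = noise_sd, label = b, mode = "pooled",
            co_substrates = setdiff(subs, sub))
          out[[length(out) + 1L]] <- simulate_assay(
            members, sub, times = times, aeration = aeration,
            noise_sd = noise_sd, label = b, mode = "control")
        }
      }
    }
    do.call(rbind, out)
  })
}
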