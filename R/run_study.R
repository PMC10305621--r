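#' Run the full pooled-screening study end to end
#'
#' Executes the whole pipeline on the synthetic study fixture: simulate
#' pooled assays and controls for both libraries, call batch hits per
#' substrate channel, deconvolve candidates under the union model, flag
#' tandem-activity and interference anomalies, decode the anomaly-implicated
#' batches as their own channel, simulate the confirmatory individual
#' assays, and account for assays used versus the conventional
#' strain-by-strain screen. Fully reproducible: the same config (seed
#' included) yields an identical report.
#'
#' @param config A [run_config()].
#' @return A `clm_study_report` list: `readouts`, `hits`, `reports`
#'   (per library/substrate `candidate_report`s), `anomalies`,
#'   `tandem_reports`, `interference_suspects`, `confirmations`
#'   (strain/substrate pairs with their simulated individual conversions),
#'   `accounting` (an `assay_plan`), `config`.
#' @examples
#' rep <- run_study(run_config(seed = 1))
#' rep$accounting
#' @export
run_study <- function(config = run_config()) {
  config <- validate_run_config(config)
  fx <- make_study_fixture(config$batch_b_mode)

  readouts <- list()
  hits <- list()
  reports <- list()
  anomalies <- list()
  tandem_reports <- list()
  n_pooled <- 0L

  for (lib in names(fx$designs)) {
    design <- fx$designs[[lib]]
    profs <- fx$profiles[[lib]]
    mixes <- fx$mixtures[fx$channels[[lib]]]
    rd <- simulate_library(design, profs, mixes,
                           times = config$timepoints,
                           noise_sd = config$noise_sd,
                           seed = config$seed + match(lib, names(fx$designs)))
    readouts[[lib]] <- rd
    n_pooled <- n_pooled + design$n_batches * length(mixes)

    hits[[lib]] <- call_hits(rd, design, threshold = config$threshold,
                             timepoint = config$call_timepoint)
    reports[[lib]] <- lapply(hits[[lib]], function(h) {
      candidates(design, h, max_actives = config$max_actives)
    })

    an <- flag_anomalies(rd, config$margin_nonmonotone,
                         config$margin_divergence)
    anomalies[[lib]] <- an

    # anomaly-implicated batches form their own decoding channel: tandem
    # (product-consuming) activity breaks the union model, so the batches
    # showing a non-monotone product are decoded directly
    nm <- an[vapply(an, function(a) a$type == "non_monotone_product",
                    logical(1))]
    for (sub in unique(vapply(nm, `[[`, character(1), "substrate"))) {
      bb <- sort(unique(vapply(nm[vapply(nm, `[[`, character(1),
                                         "substrate") == sub],
                               `[[`, character(1), "batch")))
      rep_ <- candidates(design,
                         hit_pattern(bb, design, substrate = sub),
                         max_actives = config$max_actives)
      rep_$anomalies <- nm
      rep_$tandem <- TRUE
      tandem_reports[[paste(lib, sub, sep = ".")]] <- rep_
    }
  }

  # strains exclusive to batches with control/assay divergence are kept as
  # a separate suspicion field (interference or product-oxidation), not
  # folded into the candidate sets
  suspects <- list()
  for (lib in names(anomalies)) {
    dv <- anomalies[[lib]][vapply(anomalies[[lib]], function(a) {
      a$type == "control_assay_divergence"
    }, logical(1))]
    if (length(dv) == 0L) next
    design <- fx$designs[[lib]]
    for (b in unique(vapply(dv, `[[`, character(1), "batch"))) {
      excl <- design$strain_ids[design$incidence[, b] == 1L &
                                  rowSums(design$incidence) == 1L]
      suspects[[paste(lib, b, sep = ".")]] <-
        list(batch = b, exclusive_strains = excl)
    }
  }

  # confirmations: one individual assay per distinct unresolved candidate
  conf <- list()
  all_reports <- c(unlist(reports, recursive = FALSE), tandem_reports)
  for (i_rep in seq_along(all_reports)) {
    rep_ <- all_reports[[i_rep]]
    if (!rep_$consistent || rep_$unique) next
    strains <- setdiff(unique(unlist(rep_$candidate_sets)), character(0))
    if (length(strains) < 2L) next
    lib <- sub("\\..*$", "", names(all_reports)[i_rep])
    profs <- fx$profiles[[lib]]
    names(profs) <- vapply(profs, `[[`, character(1), "strain_id")
    # tandem (product-consuming) candidates are confirmed on the racemic
    # product alcohol; reductive candidates on the ketone
    y0 <- if (isTRUE(rep_$tandem)) c(K = 0, R = 0.5, S = 0.5)
          else c(K = 1, R = 0, S = 0)
    for (s in strains) {
      if (!is.null(conf[[s]])) next   # one confirmatory assay per strain
      rd <- simulate_assay(profs[s], rep_$substrate,
                           times = config$timepoints,
                           noise_sd = config$noise_sd,
                           seed = config$seed + 1000L + length(conf),
                           y0 = y0, label = s, mode = "individual")
      conf[[s]] <- list(strain = s, substrate = rep_$substrate,
                        tandem = isTRUE(rep_$tandem), readouts = rd)
    }
  }

  n_strains_total <- sum(vapply(fx$designs, `[[`, integer(1), "n_strains"))
  accounting <- assay_count(n_strains_total,
                            n_substrate_mixtures = 0L,
                            n_substrates = length(fx$substrates),
                            n_confirmations = length(conf),
                            n_batches = 0L)
  accounting$pooled_assays <- n_pooled
  accounting$total <- n_pooled + accounting$confirmatory_assays

  structure(
    list(readouts = do.call(rbind, unname(readouts)),
         hits = hits,
         reports = reports,
         anomalies = anomalies,
         tandem_reports = tandem_reports,
         interference_suspects = suspects,
         confirmations = conf,
         accounting = accounting,
         config = unclass(config)),
    class = "clm_study_report")
}

#' @export
print.clm_study_report <- function(x, ...) {
  cat("Pooled screening study report\n")
  for (lib in names(x$hits)) {
    cat("\n[", lib, "]\n", sep = "")
    for (sub in names(x$hits[[lib]])) {
      h <- x$hits[[lib]][[sub]]
      r <- x$reports[[lib]][[sub]]
      cat(sprintf("  %-15s hits {%s} -> %s\n", sub,
                  paste(h$active_batches, collapse = ","),
                  if (!r$consistent) "inconsistent (noise/tandem suspected)"
                  else if (r$unique) paste0("unique: ",
                                            r$candidate_sets[[1L]])
                  else paste0(length(r$candidate_sets), " candidate set(s)")))
    }
    for (a in x$anomalies[[lib]]) {
      cat(sprintf("  anomaly: %s %s/%s\n", a$type, a$batch, a$substrate))
    }
  }
  if (length(x$tandem_reports)) {
    cat("\nTandem-activity channels:\n")
    for (nm_ in names(x$tandem_reports)) {
      r <- x$tandem_reports[[nm_]]
      cat("  ", nm_, ": candidates ",
          paste(vapply(r$candidate_sets, paste, character(1),
                       collapse = "+"), collapse = ", "), "\n", sep = "")
    }
  }
  if (length(x$confirmations)) {
    cat("\nConfirmatory assays:\n")
    for (cf in x$confirmations) {
      last <- cf$readouts[nrow(cf$readouts), ]
      cat(sprintf("  %s on %s: conversion %.2f at %g h\n", cf$strain,
                  cf$substrate, last$conversion, last$time_h))
    }
  }
  cat("\n")
  print(x$accounting)
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Percentages are rendered at this reporting edge; internal storage is
#' fractional throughout.
#'
#' @param report A `clm_study_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "clm_study_report"))
  out <- rapply(unclass(report), function(x) x, how = "replace")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}
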