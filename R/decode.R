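#' Call active batches from pooled readouts
#'
#' A batch is called active on a substrate when its pooled conversion at
#' `timepoint` is at least `threshold`. Per-batch scores are retained for
#' reporting. Readouts must cover every batch of the design at the chosen
#' timepoint; missing batches are an error, not a silent skip.
#'
#' @param readouts Readout table ([simulate_assay()] columns); only rows
#'   with `mode == use_mode` are used.
#' @param design A `pool_design`.
#' @param threshold Conversion threshold in (0, 1); default 0.5.
#' @param timepoint Sampling time (hours) used for calling; default 24.
#' @param use_mode Which readout mode carries the batch-level signal.
#' @return Named list (one per substrate present) of `hit_pattern` objects:
#'   `substrate`, `active_batches`, `scores` (named conversions),
#'   `threshold`, `timepoint_used`.
#' @export
call_hits <- function(readouts, design, threshold = 0.5, timepoint = 24,
                      use_mode = "pooled") {
  stopifnot(inherits(design, "pool_design"))
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  rd <- readouts[readouts$mode == use_mode & readouts$time_h == timepoint, ]
  if (nrow(rd) == 0L) {
    stop("incomplete data: no '", use_mode, "' readouts at t = ", timepoint,
         " h", call. = FALSE)
  }
  out <- list()
  for (sub in unique(rd$substrate)) {
    d <- rd[rd$substrate == sub, ]
    missing <- setdiff(design$batch_ids, d$batch_or_strain)
    if (length(missing) > 0L) {
      stop("incomplete data: substrate ", sub, " lacks batch(es) ",
           paste(missing, collapse = ", "), " at t = ", timepoint, " h",
           call. = FALSE)
    }
    scores <- d$conversion[match(design$batch_ids, d$batch_or_strain)]
    names(scores) <- design$batch_ids
    out[[sub]] <- structure(
      list(substrate = sub,
           active_batches = design$batch_ids[scores >= threshold],
           scores = scores,
           threshold = threshold,
           timepoint_used = timepoint),
      class = "hit_pattern")
  }
  out
}

#' @export
print.hit_pattern <- function(x, ...) {
  cat(x$substrate, ": hits {",
      paste(x$active_batches, collapse = ","), "} at ",
      x$timepoint_used, " h (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

hit_pattern <- function(active_batches, design, substrate = "substrate",
                        threshold = 0.5, timepoint = 24, scores = NULL) {
  stopifnot(all(active_batches %in% design$batch_ids))
  if (is.null(scores)) {
    scores <- stats::setNames(
      as.numeric(design$batch_ids %in% active_batches), design$batch_ids)
  }
  structure(list(substrate = substrate, active_batches = active_batches,
                 scores = scores, threshold = threshold,
                 timepoint_used = timepoint),
            class = "hit_pattern")
}

#' Candidate strain sets consistent with a hit pattern
#'
#' Union-model deconvolution: enumerates every strain set of size at most
#' `max_actives` whose combined batch signature equals the hit set exactly.
#' For `max_actives = 1` this is the set of strains whose signature is the
#' hit set. Candidate sets are ordered smallest first, then by strain id.
#' An empty result (a hit pattern that is no union of few signatures) is
#' returned as an explained empty report suggesting noise or tandem
#' (non-union) effects rather than raised as an error.
#'
#' @param design A `pool_design`.
#' @param hits A `hit_pattern` (or a character vector of active batch ids).
#' @param max_actives Largest active-set size considered (default 1, the
#'   usual operating assumption for one substrate channel; exhaustive
#'   enumeration is practical up to about 3).
#' @return A `candidate_report`: `substrate`, `hit_batches`,
#'   `candidate_sets` (list of character vectors), `unique` (exactly one
#'   singleton candidate), `consistent`, `note`, plus empty `anomalies` /
#'   `confirmation_plan` slots filled by the pipeline.
#' @export
candidates <- function(design, hits, max_actives = 1L) {
  stopifnot(inherits(design, "pool_design"))
  if (!inherits(hits, "hit_pattern")) {
    hits <- hit_pattern(hits, design)
  }
  stopifnot(all(hits$active_batches %in% design$batch_ids))
  sig <- signature_masks(design)
  bits <- 2^(seq_len(design$n_batches) - 1L)
  target <- sum(bits[design$batch_ids %in% hits$active_batches])

  sets <- list()
  if (target == 0) {
    sets <- list(character(0))   # no activity: the empty set explains it
  } else {
    # only strains whose signature is contained in the hit set can be active
    feas <- which(bitwAnd(sig, bitwNot(as.integer(target))) == 0L)
    for (size in seq_len(min(max_actives, length(feas)))) {
      for (ix in utils::combn(feas, size, simplify = FALSE)) {
        if (Reduce(bitwOr, sig[ix], 0L) == target) {
          sets[[length(sets) + 1L]] <- design$strain_ids[ix]
        }
      }
    }
    ord <- order(lengths(sets),
                 vapply(sets, function(s) paste(s, collapse = ","),
                        character(1)))
    sets <- sets[ord]
  }
  consistent <- length(sets) > 0L
  note <- if (!consistent) {
    paste0("no union of <= ", max_actives, " strain signatures equals the ",
           "hit set {", paste(hits$active_batches, collapse = ","),
           "}; suspect measurement noise or tandem (non-union) activity")
  } else {
    NA_character_
  }
  structure(
    list(substrate = hits$substrate,
         hit_batches = hits$active_batches,
         max_actives = as.integer(max_actives),
         candidate_sets = sets,
         unique = sum(lengths(sets) == 1L) == 1L && length(sets) == 1L,
         consistent = consistent,
         note = note,
         anomalies = list(),
         confirmation_plan = character(0)),
    class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidates for ", x$substrate, " (hits {",
      paste(x$hit_batches, collapse = ","), "}):\n", sep = "")
  if (!x$consistent) {
    cat("  none -", x$note, "\n")
  } else {
    for (s in x$candidate_sets) {
      cat("  {", paste(s, collapse = ", "), "}\n", sep = "")
    }
    if (x$unique) cat("  -> unique assignment\n")
  }
  if (length(x$anomalies)) {
    cat("  anomalies:",
        paste(vapply(x$anomalies, function(a) {
          paste0(a$type, "@", a$batch)
        }, character(1)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flag tandem-activity and interference anomalies in readouts
#'
#' Two checks, run per batch/substrate/aeration group:
#' \describe{
#' \item{non_monotone_product}{the pooled product (conversion) at a later
#'   timepoint falls below an earlier one by more than
#'   `margin_nonmonotone`; the signature of a product being consumed again
#'   (e.g. an enantioselective oxidation following the reduction). Skipped
#'   with a notice when only one timepoint is available.}
#' \item{control_assay_divergence}{pooled (mixture) and control (single
#'   substrate) conversions differ by more than `margin_divergence` at a
#'   matched timepoint; the signature of substrate-mixture interference.}
#' }
#'
#' @param readouts Readout table with `pooled` and (optionally) `control`
#'   rows.
#' @param margin_nonmonotone Absolute product drop that triggers a flag.
#' @param margin_divergence Absolute control-assay difference that triggers
#'   a flag.
#' @return List of anomaly records `list(batch, substrate, type, evidence)`;
#'   attribute `notice` carries skip notices.
#' @export
flag_anomalies <- function(readouts, margin_nonmonotone = 0.10,
                           margin_divergence = 0.20) {
  out <- list()
  notices <- character(0)
  pooled <- readouts[readouts$mode == "pooled", ]
  ctrl <- readouts[readouts$mode == "control", ]
  for (b in unique(pooled$batch_or_strain)) {
    for (sub in unique(pooled$substrate[pooled$batch_or_strain == b])) {
      d <- pooled[pooled$batch_or_strain == b & pooled$substrate == sub, ]
      d <- d[order(d$time_h), ]
      if (nrow(d) < 2L) {
        notices <- c(notices, paste0(
          "non_monotone check skipped for ", b, "/", sub,
          ": single timepoint"))
      } else {
        drops <- d$conversion[-nrow(d)] - d$conversion[-1L]
        worst <- which.max(drops)
        if (drops[worst] > margin_nonmonotone) {
          out[[length(out) + 1L]] <- list(
            batch = b, substrate = sub, type = "non_monotone_product",
            evidence = c(t_early = d$time_h[worst],
                         product_early = d$conversion[worst],
                         t_late = d$time_h[worst + 1L],
                         product_late = d$conversion[worst + 1L]))
        }
      }
      cc <- ctrl[ctrl$batch_or_strain == b & ctrl$substrate == sub, ]
      both <- intersect(d$time_h, cc$time_h)
      for (tt in both) {
        a_conv <- d$conversion[d$time_h == tt][1L]
        c_conv <- cc$conversion[cc$time_h == tt][1L]
        if (abs(c_conv - a_conv) > margin_divergence) {
          out[[length(out) + 1L]] <- list(
            batch = b, substrate = sub, type = "control_assay_divergence",
            evidence = c(time_h = tt, control = c_conv, assay = a_conv))
        }
      }
    }
  }
  attr(out, "notice") <- notices
  out
}

#' Plan confirmatory individual assays for a candidate report
#'
#' When deconvolution is ambiguous, every distinct candidate strain gets
#' one individual assay; a unique assignment needs none. An inconsistent
#' (empty) report falls back to covering every strain of the implicated
#' batches, with a warning. Returns the assay accounting alongside.
#'
#' @param report A `candidate_report`.
#' @param design The `pool_design` decoded against.
#' @param n_substrates Number of substrates for the conventional-count
#'   comparison.
#' @param pooled_done Pooled incubations already performed.
#' @return List with `confirmation_strains` and `plan` (an `assay_plan`).
#' @export
plan_confirmation <- function(report, design, n_substrates = 1L,
                              pooled_done = design$n_batches) {
  stopifnot(inherits(report, "candidate_report"),
            inherits(design, "pool_design"))
  strains <- unique(unlist(report$candidate_sets))
  if (!report$consistent) {
    implicated <- report$hit_batches
    strains <- design$strain_ids[
      rowSums(design$incidence[, implicated, drop = FALSE]) > 0L]
    warning("inconsistent hit pattern: confirmation plan falls back to all ",
            length(strains), " strain(s) of batches {",
            paste(implicated, collapse = ","), "}", call. = FALSE)
  } else if (report$unique) {
    strains <- character(0)
  }
  plan <- assay_count(design, n_substrate_mixtures = 0L,
                      n_substrates = n_substrates,
                      n_confirmations = length(strains))
  plan$pooled_assays <- as.integer(pooled_done)
  plan$total <- plan$pooled_assays + plan$confirmatory_assays
  list(confirmation_strains = strains, plan = plan)
}
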