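#' Read and write pooling-design matrices as CSV
#'
#' The on-disk form is a comma-separated, UTF-8, header-required table: a
#' `strain_id` column followed by one 0/1 column per batch. Reading
#' validates entries and pool sizes; malformed content is rejected with the
#' offending row named.
#'
#' @param design A `pool_design`.
#' @param path File path.
#' @return `read_design` returns a `pool_design`; `write_design` its path,
#'   invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "pool_design"))
  df <- data.frame(strain_id = design$strain_ids, design$incidence,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"strain_id" %in% names(df) || ncol(df) < 2L) {
    stop("design CSV needs a strain_id column plus batch columns",
         call. = FALSE)
  }
  inc <- as.matrix(df[, setdiff(names(df), "strain_id"), drop = FALSE])
  bad <- which(matrix(!(inc %in% c(0, 1)), nrow(inc)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("design CSV row ", bad[1L, 1L] + 1L,
         ": entries must be 0 or 1", call. = FALSE)
  }
  storage.mode(inc) <- "integer"
  rownames(inc) <- df$strain_id
  cs <- colSums(inc)
  if (length(unique(cs)) != 1L) {
    stop("design CSV batches have unequal pool sizes: ",
         paste(cs, collapse = ", "), call. = FALSE)
  }
  if (any(rowSums(inc) < 1L)) {
    stop("design CSV: every strain must appear in at least one batch",
         call. = FALSE)
  }
  new_pool_design(inc, cs[1L])
}

#' Read and write assay readout tables as CSV
#'
#' Columns: `batch_or_strain`, `substrate`, `time_h`, `conversion`,
#' `alcohol_ee`, `aeration`, `mode`. Reading validates ranges
#' (conversion in [0,1], |ee| <= 1, known aeration/mode levels) and names
#' the first offending row.
#'
#' @param readouts Readout data frame.
#' @param path File path.
#' @return `read_readouts` returns the validated data frame;
#'   `write_readouts` its path, invisibly.
#' @export
write_readouts <- function(readouts, path) {
  utils::write.csv(readouts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

readout_cols <- c("batch_or_strain", "substrate", "time_h", "conversion",
                  "alcohol_ee", "aeration", "mode")

#' @rdname write_readouts
#' @export
read_readouts <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(readout_cols, names(df))
  if (length(missing) > 0L) {
    stop("readout CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  chk <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0L) {
      stop("readout CSV row ", bad[1L] + 1L, ": ", what, call. = FALSE)
    }
  }
  chk(is.finite(df$time_h) & df$time_h >= 0, "time_h must be >= 0")
  chk(is.finite(df$conversion) & df$conversion >= 0 & df$conversion <= 1,
      "conversion must lie in [0, 1]")
  chk(is.na(df$alcohol_ee) | abs(df$alcohol_ee) <= 1,
      "|alcohol_ee| must be <= 1")
  chk(df$aeration %in% c("aerobic", "anaerobic"),
      "aeration must be aerobic or anaerobic")
  chk(df$mode %in% c("pooled", "control", "individual"),
      "mode must be pooled, control or individual")
  df[readout_cols]
}

#' Run configuration for the screening pipeline
#'
#' Bundles the tunables of a full study run. Fractions are stored (and
#' validated) as fractions; they are rendered as percentages only at the
#' reporting edge.
#'
#' @param seed Integer seed driving every random draw of the run.
#' @param threshold Batch-activity conversion threshold in (0, 1).
#' @param margin_nonmonotone,margin_divergence Anomaly margins in (0, 1).
#' @param timepoints Sorted, non-empty sampling times (hours).
#' @param call_timepoint Timepoint used for hit calling.
#' @param noise_sd Multiplicative conversion-noise sd.
#' @param max_actives Decoder search depth.
#' @param batch_b_mode Fixture hypothesis for the batch-B effect.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L, threshold = 0.5,
                       margin_nonmonotone = 0.10, margin_divergence = 0.20,
                       timepoints = c(4, 24), call_timepoint = 24,
                       noise_sd = 0.03, max_actives = 1L,
                       batch_b_mode = "oxidation") {
  cfg <- list(seed = as.integer(seed), threshold = threshold,
              margin_nonmonotone = margin_nonmonotone,
              margin_divergence = margin_divergence,
              timepoints = as.numeric(timepoints),
              call_timepoint = as.numeric(call_timepoint),
              noise_sd = noise_sd, max_actives = as.integer(max_actives),
              batch_b_mode = batch_b_mode)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  for (f in c("threshold", "margin_nonmonotone", "margin_divergence")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop("config field ", f, " must lie in (0, 1)", call. = FALSE)
    }
  }
  tp <- cfg$timepoints
  if (length(tp) == 0L || is.unsorted(tp, strictly = TRUE) || any(tp < 0)) {
    stop("config timepoints must be non-empty, sorted and >= 0",
         call. = FALSE)
  }
  if (!cfg$call_timepoint %in% tp) {
    stop("config call_timepoint must be one of the timepoints",
         call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("config noise_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read/write a run configuration as YAML
#'
#' @param cfg A `run_config`.
#' @param path File path.
#' @return `read_run_config` returns a validated `run_config`;
#'   `write_run_config` its path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(run_config()), raw)
  validate_run_config(cfg)
}
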