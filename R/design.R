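#' Build a random strain-by-batch pooling design
#'
#' Constructs a combinatorial-library pooling design: `n_strains` strains are
#' distributed over `n_batches` incubation batches of `pool_size` members
#' each. Replication per strain is the floor/ceiling of
#' `n_batches * pool_size / n_strains`, so for the canonical 12-strain,
#' 4-batch, pool-size-5 library 8 strains appear in two batches and 4 in one.
#' A strain's replicate copies always land in distinct batches, so each
#' strain has a well-defined batch signature (the set of batches containing
#' it).
#'
#' Construction is a seeded random shuffle of strain copies into batch
#' slots, retried until the within-batch-uniqueness (and, optionally,
#' distinct-signature) constraints hold. Infeasible requests fail with a
#' capacity error rather than silently relaxing a constraint.
#'
#' @param n_strains Number of strains (> 0).
#' @param n_batches Number of incubation batches (> 0).
#' @param pool_size Members per batch (> 0).
#' @param seed Optional integer seed; the same seed reproduces the design.
#' @param distinct_signatures If `TRUE`, require all strain signatures to be
#'   pairwise distinct. Note that with replication r over b batches at most
#'   `sum(choose(b, unique(r)))` distinct signatures exist; an impossible
#'   request errors.
#' @param strain_ids,batch_ids Optional label vectors; defaults are
#'   `s01, s02, ...` and consecutive letters `A, B, ...`.
#' @return An object of class `pool_design`: a list with `incidence` (binary
#'   strain-by-batch matrix), `n_strains`, `n_batches`, `pool_size`,
#'   `strain_ids`, `batch_ids`, `seed`.
#' @examples
#' d <- build_design(12, 4, 5, seed = 1)
#' colSums(d$incidence)   # every batch holds pool_size strains
#' table(rowSums(d$incidence))  # 8 strains twice, 4 once
#' @export
build_design <- function(n_strains, n_batches, pool_size, seed = NULL,
                         distinct_signatures = FALSE,
                         strain_ids = NULL, batch_ids = NULL) {
  stopifnot(length(n_strains) == 1L, n_strains >= 1,
            length(n_batches) == 1L, n_batches >= 1,
            length(pool_size) == 1L, pool_size >= 1)
  n_strains <- as.integer(n_strains)
  n_batches <- as.integer(n_batches)
  pool_size <- as.integer(pool_size)
  slots <- n_batches * pool_size
  if (slots < n_strains) {
    stop("capacity error: ", slots, " pool slots cannot hold ",
         n_strains, " strains", call. = FALSE)
  }
  if (pool_size > n_strains) {
    stop("capacity error: pool_size ", pool_size, " exceeds ", n_strains,
         " strains (a strain cannot appear twice in one batch)",
         call. = FALSE)
  }
  r_lo <- slots %/% n_strains
  n_hi <- slots %% n_strains          # strains replicated r_lo + 1 times
  r_hi <- if (n_hi > 0L) r_lo + 1L else r_lo
  if (r_hi > n_batches) {
    stop("capacity error: replication ", r_hi, " exceeds ", n_batches,
         " batches", call. = FALSE)
  }
  if (distinct_signatures) {
    reps <- unique(c(r_lo, r_hi))
    capacity <- sum(choose(n_batches, reps))
    if (capacity < n_strains) {
      stop("capacity error: only ", capacity, " distinct signatures of size ",
           paste(reps, collapse = " or "), " exist over ", n_batches,
           " batches; ", n_strains, " needed", call. = FALSE)
    }
  }
  if (is.null(strain_ids)) {
    strain_ids <- sprintf("s%02d", seq_len(n_strains))
  }
  if (is.null(batch_ids)) {
    batch_ids <- make_batch_labels(n_batches)
  }
  stopifnot(length(strain_ids) == n_strains, !anyDuplicated(strain_ids),
            length(batch_ids) == n_batches, !anyDuplicated(batch_ids))

  reps_per_strain <- c(rep(r_hi, n_hi), rep(r_lo, n_strains - n_hi))
  inc <- with_seed(seed, {
    # which strains carry the extra replicate is itself randomised
    reps_per_strain <- sample(reps_per_strain)
    copies <- rep(seq_len(n_strains), times = reps_per_strain)
    batch_of_slot <- rep(seq_len(n_batches), each = pool_size)
    found <- NULL
    for (attempt in seq_len(2000L)) {
      assign_ <- sample(copies)
      m <- matrix(0L, n_strains, n_batches)
      ok <- TRUE
      for (b in seq_len(n_batches)) {
        members <- assign_[batch_of_slot == b]
        if (anyDuplicated(members)) { ok <- FALSE; break }
        m[members, b] <- 1L
      }
      if (!ok) next
      if (distinct_signatures &&
          anyDuplicated(apply(m, 1L, paste, collapse = ""))) next
      found <- m
      break
    }
    found
  })
  if (is.null(inc)) {
    stop("capacity error: could not satisfy design constraints after ",
         "bounded retries (constraints may be jointly infeasible)",
         call. = FALSE)
  }
  dimnames(inc) <- list(strain_ids, batch_ids)
  new_pool_design(inc, pool_size, seed)
}

new_pool_design <- function(incidence, pool_size, seed = NULL) {
  structure(
    list(incidence = incidence,
         n_strains = nrow(incidence),
         n_batches = ncol(incidence),
         pool_size = as.integer(pool_size),
         strain_ids = rownames(incidence),
         batch_ids = colnames(incidence),
         seed = seed),
    class = "pool_design")
}

#' Assemble a pooling design from explicit batch memberships
#'
#' @param memberships Named list: one character vector of batch ids per
#'   strain id.
#' @param batch_ids Batch labels, in column order.
#' @param pool_size Expected members per batch (checked).
#' @return A `pool_design`.
#' @export
design_from_memberships <- function(memberships, batch_ids, pool_size) {
  stopifnot(is.list(memberships), !is.null(names(memberships)))
  inc <- matrix(0L, length(memberships), length(batch_ids),
                dimnames = list(names(memberships), batch_ids))
  for (s in names(memberships)) {
    b <- memberships[[s]]
    stopifnot(all(b %in% batch_ids), !anyDuplicated(b), length(b) >= 1L)
    inc[s, b] <- 1L
  }
  if (!all(colSums(inc) == pool_size)) {
    stop("batch memberships do not give ", pool_size,
         " members in every batch", call. = FALSE)
  }
  new_pool_design(inc, pool_size)
}

make_batch_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else sprintf("B%03d", seq_len(n))
}

# Evaluate `expr` under a temporary RNG state; NULL seed = use current RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.pool_design <- function(x, ...) {
  cat("Pooling design:", x$n_strains, "strains x", x$n_batches,
      "batches, pool size", x$pool_size, "\n")
  reps <- table(rowSums(x$incidence))
  cat("Replication:",
      paste(sprintf("%s strain(s) in %s batch(es)", reps, names(reps)),
            collapse = ", "), "\n")
  print(x$incidence)
  invisible(x)
}

signature_strings <- function(design) {
  apply(design$incidence, 1L, function(r) {
    paste(design$batch_ids[r == 1L], collapse = ",")
  })
}

# bitmask of each strain's signature (n_batches <= 30)
signature_masks <- function(design) {
  bits <- 2^(seq_len(design$n_batches) - 1L)
  as.integer(design$incidence %*% bits)
}

#' Validate the decodability of a pooling design
#'
#' Reports whether all strain signatures are distinct and whether the design
#' is `max_actives`-separable: unions of up to `max_actives` strain
#' signatures are pairwise distinct, the condition under which batch-level
#' hit patterns identify the active set unambiguously. Checked by exhaustive
#' subset enumeration (designs here are small).
#'
#' @param design A `pool_design`.
#' @param max_actives Largest number of simultaneously active strains to
#'   guarantee decodability for.
#' @return A list with `signatures_distinct`, `separable`, `collisions`
#'   (list of strain-id groups sharing one signature) and
#'   `ambiguous_unions` (list of strain-set pairs with identical unions).
#' @export
validate_design <- function(design, max_actives = 1L) {
  stopifnot(inherits(design, "pool_design"), max_actives >= 1L)
  sig <- signature_masks(design)
  names(sig) <- design$strain_ids
  coll <- split(design$strain_ids, sig)
  coll <- unname(coll[lengths(coll) > 1L])

  subsets <- enumerate_subsets(design$n_strains, max_actives)
  unions <- vapply(subsets, function(ix) {
    Reduce(bitwOr, sig[ix], 0L)
  }, numeric(1))
  dup_groups <- split(seq_along(subsets), unions)
  dup_groups <- dup_groups[lengths(dup_groups) > 1L]
  ambiguous <- lapply(unname(dup_groups), function(g) {
    lapply(subsets[g], function(ix) design$strain_ids[ix])
  })
  list(signatures_distinct = length(coll) == 0L,
       separable = length(ambiguous) == 0L,
       max_actives = as.integer(max_actives),
       collisions = coll,
       ambiguous_unions = ambiguous)
}

# all non-empty subsets of 1..n of size <= k, as integer vectors
enumerate_subsets <- function(n, k) {
  out <- list()
  for (size in seq_len(min(k, n))) {
    out <- c(out, utils::combn(n, size, simplify = FALSE))
  }
  out
}

#' Assay-count economics of pooled versus conventional screening
#'
#' One pooled round costs `n_batches * n_substrate_mixtures` incubations;
#' the conventional strain-by-strain approach costs
#' `n_strains * n_substrates`. Confirmatory individual assays are added to
#' the pooled total.
#'
#' @param design A `pool_design`, or an integer number of strains together
#'   with `n_batches`.
#' @param n_substrate_mixtures Substrate mixtures incubated with each batch.
#' @param n_substrates Individual substrates (for the conventional count).
#' @param n_confirmations Confirmatory single-strain assays.
#' @param n_batches Required when `design` is given as a strain count.
#' @return An `assay_plan`: list with `pooled_assays`,
#'   `confirmatory_assays`, `total`, `conventional`.
#' @examples
#' d <- build_design(12, 4, 5, seed = 1)
#' assay_count(d, 1, 1, 2)  # total 6 vs conventional 12
#' @export
assay_count <- function(design, n_substrate_mixtures = 1L, n_substrates = 1L,
                        n_confirmations = 0L, n_batches = NULL) {
  if (inherits(design, "pool_design")) {
    n_strains <- design$n_strains
    n_batches <- design$n_batches
  } else {
    n_strains <- as.integer(design)
    if (is.null(n_batches)) stop("n_batches required with a strain count")
  }
  stopifnot(n_substrate_mixtures >= 0, n_substrates >= 0,
            n_confirmations >= 0)
  pooled <- as.integer(n_batches) * as.integer(n_substrate_mixtures)
  plan <- list(pooled_assays = pooled,
               confirmatory_assays = as.integer(n_confirmations),
               total = pooled + as.integer(n_confirmations),
               conventional = n_strains * as.integer(n_substrates))
  class(plan) <- "assay_plan"
  plan
}

#' @export
print.assay_plan <- function(x, ...) {
  cat("Assay plan: ", x$pooled_assays, " pooled + ",
      x$confirmatory_assays, " confirmatory = ", x$total,
      " assays (conventional: ", x$conventional, ")\n", sep = "")
  invisible(x)
}
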