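`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent brute-force oracles, deliberately built on character-set
# algebra rather than the package's bitmask path.

# all candidate strain sets of size <= d whose signature union equals hits
oracle_candidates <- function(design, hit_batches, max_actives) {
  sigs <- lapply(design$strain_ids, function(s) {
    design$batch_ids[design$incidence[s, ] == 1L]
  })
  names(sigs) <- design$strain_ids
  target <- sort(hit_batches)
  if (length(target) == 0L) return(list(character(0)))
  out <- list()
  for (size in seq_len(max_actives)) {
    for (set in utils::combn(design$strain_ids, size, simplify = FALSE)) {
      u <- sort(unique(unlist(sigs[set])))
      if (identical(u, target)) out[[length(out) + 1L]] <- set
    }
  }
  out
}

# is the design d-separable? (unions of <= d signatures pairwise distinct)
oracle_separable <- function(design, max_actives) {
  sigs <- lapply(design$strain_ids, function(s) {
    design$batch_ids[design$incidence[s, ] == 1L]
  })
  names(sigs) <- design$strain_ids
  seen <- character(0)
  for (size in seq_len(max_actives)) {
    for (set in utils::combn(design$strain_ids, size, simplify = FALSE)) {
      key <- paste(sort(unique(unlist(sigs[set]))), collapse = ",")
      if (key %in% seen) return(FALSE)
      seen <- c(seen, key)
    }
  }
  TRUE
}

# canonical string form of a list of candidate sets, for comparison
canon_sets <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = "+"),
              character(1)))
}

expect_same_sets <- function(a, b) {
  expect_identical(canon_sets(a), canon_sets(b))
}
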