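fixture_readouts <- function(noise_sd = 0, seed = NULL) {
  fx <- make_study_fixture()
  list(fx = fx,
       clm1 = simulate_library(fx$designs$clm1, fx$profiles$clm1,
                               fx$mixtures[fx$channels$clm1],
                               noise_sd = noise_sd, seed = seed),
       clm2 = simulate_library(fx$designs$clm2, fx$profiles$clm2,
                               fx$mixtures[fx$channels$clm2],
                               noise_sd = noise_sd, seed = seed))
}

test_that("call_hits thresholds batch conversions per substrate", {
  rx <- fixture_readouts()
  hits1 <- call_hits(rx$clm1, rx$fx$designs$clm1, threshold = 0.5,
                     timepoint = 24)
  expect_identical(hits1[["2-octanone"]]$active_batches, "D")
  expect_identical(hits1[["propiophenone"]]$active_batches, c("A", "D"))
  expect_identical(hits1[["acetonaphthone"]]$active_batches, c("A", "D"))

  hits2 <- call_hits(rx$clm2, rx$fx$designs$clm2, threshold = 0.5,
                     timepoint = 4)
  expect_true("E" %in% hits2[["3-octanone"]]$active_batches)

  # all-zero readouts give an empty hit set
  flat <- rx$clm1
  flat$conversion <- 0
  h0 <- call_hits(flat, rx$fx$designs$clm1)
  expect_length(h0[["2-octanone"]]$active_batches, 0)

  # a missing batch is an explicit incomplete-data error
  expect_error(call_hits(rx$clm1[rx$clm1$batch_or_strain != "C", ],
                         rx$fx$designs$clm1),
               "incomplete")
  expect_error(call_hits(rx$clm1, rx$fx$designs$clm1, threshold = 1.2),
               "threshold")
})

test_that("fixture hit patterns decode to the expected candidate sets", {
  fx <- make_study_fixture()
  r_D <- candidates(fx$designs$clm1, "D")
  expect_true(r_D$unique)
  expect_identical(r_D$candidate_sets[[1L]], "s01")

  r_AD <- candidates(fx$designs$clm1, c("A", "D"))
  expect_false(r_AD$unique)
  expect_same_sets(r_AD$candidate_sets, list("s02", "s03"))

  r_EF <- candidates(fx$designs$clm2, c("E", "F"))
  expect_same_sets(r_EF$candidate_sets, list("t02", "t03"))

  # a hit pattern that is no union of signatures is an explained empty
  r_bad <- candidates(fx$designs$clm1, c("B", "D"), max_actives = 1)
  expect_false(r_bad$consistent)
  expect_match(r_bad$note, "tandem")
  # ... but is explained by two simultaneous actives
  r_bad2 <- candidates(fx$designs$clm1, c("B", "D"), max_actives = 2)
  expect_true(r_bad2$consistent)
  expect_true(all(vapply(r_bad2$candidate_sets, length, integer(1)) == 2L))
})

test_that("decoder agrees with brute-force enumeration over small designs", {
  set.seed(31)
  cases <- expand.grid(n_s = c(4, 8, 12, 16), n_b = c(3, 4, 6))
  for (i in seq_len(nrow(cases))) {
    n_b <- cases$n_b[i]
    k <- as.integer(ceiling(cases$n_s[i] / n_b))
    d <- build_design(cases$n_s[i], n_b, k, seed = 400 + i)
    for (hit_mask in 0:(2^n_b - 1)) {
      hit <- d$batch_ids[bitwAnd(hit_mask, 2^(seq_len(n_b) - 1)) > 0]
      for (ma in 1:2) {
        got <- candidates(d, hit, max_actives = ma)$candidate_sets
        want <- oracle_candidates(d, hit, ma)
        expect_same_sets(got, want)
      }
    }
  }
})

test_that("a single active strain is always recovered, noiselessly", {
  for (seed in 1:200) {
    d <- build_design(8, 6, 3, seed = seed, distinct_signatures = TRUE)
    truth <- d$strain_ids[1L + seed %% 8L]
    profs <- lapply(d$strain_ids, function(s) {
      if (s == truth) {
        strain_profile(s, list(ket = list(k_red_R = 0.3)))
      } else {
        strain_profile(s)
      }
    })
    rd <- simulate_library(d, profs, list(m = "ket"), noise_sd = 0)
    h <- call_hits(rd, d, threshold = 0.5, timepoint = 24)[["ket"]]
    rep_ <- candidates(d, h)
    expect_true(any(vapply(rep_$candidate_sets, function(s) truth %in% s,
                           logical(1))))
    if (validate_design(d, 1)$separable) {
      expect_true(rep_$unique)
      expect_identical(rep_$candidate_sets[[1L]], truth)
    }
  }
})

test_that("raising the threshold never enlarges the hit set", {
  rx <- fixture_readouts(noise_sd = 0.03, seed = 8)
  prev <- NULL
  for (th in c(0.2, 0.4, 0.6, 0.8)) {
    h <- call_hits(rx$clm1, rx$fx$designs$clm1, threshold = th)
    hitset <- h[["propiophenone"]]$active_batches
    if (!is.null(prev)) expect_true(all(hitset %in% prev))
    prev <- hitset
  }
})

test_that("flag_anomalies catches the two anomaly classes", {
  mk <- function(b, sub, t, conv, mode) {
    data.frame(batch_or_strain = b, substrate = sub, time_h = t,
               conversion = conv, alcohol_ee = NA_real_,
               aeration = "aerobic", mode = mode)
  }
  # product falls 0.75 -> 0.25: non-monotone flag
  rd <- rbind(mk("E", "ace", 4, 0.75, "pooled"),
              mk("E", "ace", 24, 0.25, "pooled"))
  an <- flag_anomalies(rd)
  expect_length(an, 1)
  expect_identical(an[[1L]]$type, "non_monotone_product")
  expect_identical(an[[1L]]$batch, "E")

  # control 0.90 vs assay 0.51: divergence flag
  rd <- rbind(mk("B", "oct", 24, 0.51, "pooled"),
              mk("B", "oct", 24, 0.90, "control"))
  an <- flag_anomalies(rd)
  types <- vapply(an, `[[`, character(1), "type")
  expect_true("control_assay_divergence" %in% types)
  expect_false("non_monotone_product" %in% types)
  expect_match(attr(an, "notice"), "single timepoint", all = FALSE)

  # identical curves: clean
  rd <- rbind(mk("A", "oct", c(4, 24), c(0.3, 0.8), "pooled"),
              mk("A", "oct", c(4, 24), c(0.3, 0.8), "control"))
  expect_length(flag_anomalies(rd), 0)
})

test_that("confirmation plans size with ambiguity", {
  fx <- make_study_fixture()
  d <- fx$designs$clm1

  two <- candidates(d, c("A", "D"))
  pl <- plan_confirmation(two, d, n_substrates = 1, pooled_done = 4)
  expect_identical(sort(pl$confirmation_strains), c("s02", "s03"))
  expect_identical(pl$plan$total, 6L)
  expect_identical(pl$plan$conventional, 12L)

  uni <- candidates(d, "D")
  expect_length(plan_confirmation(uni, d)$confirmation_strains, 0)

  bad <- candidates(d, c("B", "D"), max_actives = 1)
  expect_warning(pl3 <- plan_confirmation(bad, d), "fall")
  # fallback covers every strain of the implicated batches
  expect_setequal(pl3$confirmation_strains,
                  d$strain_ids[rowSums(d$incidence[, c("B", "D")]) > 0])
})
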