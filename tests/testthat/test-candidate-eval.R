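test_that("cosine spectral similarity on unit bins", {
  a <- ms_spectrum(c(73, 147), c(10, 5))
  expect_equal(spectral_similarity(a, a), 1)
  b <- ms_spectrum(c(200, 250), c(1, 1))
  expect_equal(spectral_similarity(a, b), 0)
  one <- ms_spectrum(73, 1)
  two <- ms_spectrum(c(73, 147), c(1, 1))
  expect_equal(spectral_similarity(one, two), 1 / sqrt(2), tolerance = 1e-12)
})

test_that("ppm error matches its closed form", {
  expect_equal(ppm_error(100, 100), 0)
  expect_equal(ppm_error(100.0010, 100.0000), 10, tolerance = 1e-6)
  set.seed(3)
  m1 <- runif(50, 100, 900); m2 <- m1 + rnorm(50, 0, 0.01)
  expect_equal(ppm_error(m2, m1), 1e6 * abs(m2 - m1) / m1)
  expect_error(ppm_error(100, 0), "> 0")
})

test_that("CI candidate sets collect exact-mass matches", {
  lib <- tiny_library()
  # no two records in the tiny library share a mass: all sets are singletons
  cs <- build_candidate_sets(lib, "ci", n_seeds = 3, rng_seed = 1,
                             coverage_floor = 0.4)
  expect_true(all(vapply(cs$sets, function(s) length(s$pim_ids), integer(1))
                  == 0L))
  # an identical-mass record joins the seed's set
  recs <- rbind(as.data.frame(lib),
                within(as.data.frame(lib)[1, ], {
                  record_id <- "iso"; base_id <- "iso"; smiles <- "C(C)O"
                }))
  lib2 <- derivative_library(recs)
  cs2 <- build_candidate_sets(lib2, "ci", n_seeds = nrow(lib2) - 1,
                              rng_seed = 2, coverage_floor = 0)
  sizes <- vapply(cs2$sets, function(s) 1L + length(s$pim_ids), integer(1))
  seeds <- vapply(cs2$sets, `[[`, character(1), "seed_record_id")
  expect_true(all(sizes[seeds %in% c("eth0", "iso")] == 2))
})

test_that("isobar clusters in the generator share formulas exactly", {
  gen <- fixture_gen()
  lib <- gen$library
  cl <- split(seq_len(nrow(lib)), gen$truth$cluster_id)
  multi <- cl[vapply(cl, length, integer(1)) > 1]
  expect_gt(length(multi), 0)
  for (g in multi[1:min(20, length(multi))]) {
    expect_lt(max(ppm_error(lib$monoisotopic_mass[g],
                            lib$monoisotopic_mass[g[1]])), 1e-6)
  }
  # candidate sets contain the seed's whole formula cluster, and nothing
  # outside the mass tolerance (near-isobars across clusters may join)
  cs <- build_candidate_sets(lib, "ci", n_seeds = 15, rng_seed = 3,
                             coverage_floor = 0.5)
  for (s in cs$sets) {
    i <- match(s$seed_record_id, lib$record_id)
    cluster <- lib$record_id[gen$truth$cluster_id == gen$truth$cluster_id[i]]
    members <- c(s$seed_record_id, s$pim_ids)
    expect_true(all(cluster %in% members))
    m <- lib$monoisotopic_mass[match(members, lib$record_id)]
    expect_true(all(ppm_error(m, lib$monoisotopic_mass[i]) <= 10))
  }
})

test_that("the coverage floor guards the training fraction", {
  lib <- fixture_gen()$library
  expect_error(
    build_candidate_sets(lib, "ci", n_seeds = nrow(lib) - 1, rng_seed = 1,
                         coverage_floor = 0.8),
    "fewer seed")
  cs <- build_candidate_sets(lib, "ci", n_seeds = 6, rng_seed = 1)
  members <- unlist(lapply(cs$sets, function(s)
    c(s$seed_record_id, s$pim_ids)))
  expect_length(intersect(cs$train_ids, members), 0)
  expect_equal(cs$coverage, length(cs$train_ids) / nrow(lib))
})

test_that("EI candidate sets use the spectral threshold", {
  gen <- fixture_gen()
  sp <- fixture_spectra()
  cs <- build_candidate_sets(gen$library, "ei", n_seeds = 5, rng_seed = 2,
                             spectra = sp, coverage_floor = 0.5)
  for (s in cs$sets) {
    for (pim in s$pim_ids)
      expect_gte(spectral_similarity(sp[[pim]], sp[[s$seed_record_id]]),
                 0.8 - 1e-9)
  }
  expect_error(build_candidate_sets(gen$library, "ei", n_seeds = 5,
                                    rng_seed = 2),
               "requires spectra")
})

test_that("ranking orders by error with pessimistic tie handling", {
  rc <- ranked_from_errors(1, c(0.5, 5))
  expect_identical(attr(rc, "rank_of_true"), 2L)
  expect_true(all(diff(rc$rel_error_pct) >= 0))
  rc1 <- ranked_from_errors(0.1, c(2, 3, 4))
  expect_identical(attr(rc1, "rank_of_true"), 1L)
  # C = 1 is always rank 1
  solo <- ranked_from_errors(2, numeric(0))
  expect_identical(attr(solo, "rank_of_true"), 1L)
  # an exact tie never favours the true identity
  tie <- ranked_from_errors(2, c(2, -2))
  expect_identical(attr(tie, "rank_of_true"), 3L)
  set.seed(4)
  for (i in 1:20) {
    e <- round(runif(4, 0, 10), 3)
    rc2 <- ranked_from_errors(e[1], e[-1])
    expect_equal(rc2$rel_error_pct, sort(abs(e)), tolerance = 1e-9)
  }
  set <- structure(list(mode = "ci", seed_record_id = "T",
                        pim_ids = "P1", reference_ri = 1000),
                   class = "candidate_set")
  expect_error(rank_candidates(set, c(T = 1000)), "missing prediction.*P1")
})

test_that("top-k summary groups by candidate count", {
  ranked <- c(lapply(1:5, function(i) ranked_from_errors(0.1, 5)),
              lapply(1:4, function(i) ranked_from_errors(0.1, c(5, 6))),
              lapply(1:3, function(i) ranked_from_errors(0.1, c(5, 6, 7, 8))),
              list(ranked_from_errors(1, numeric(0))))  # C=1, excluded
  tk <- topk_summary(ranked)
  expect_equal(tk$n_sets, c(5L, 4L, 3L))
  expect_equal(tk$rank1, c(1, 1, 1))
  expect_equal(tk$top3, c(1, 1, 1))
  sums <- rowSums(tk[, c("rank1", "rank2", "rank3", "beyond3")])
  expect_equal(sums, rep(1, 3))
})

test_that("uniform-random ranking puts the truth first half the time at C=2", {
  set.seed(6)
  ranked <- lapply(1:2000, function(i) {
    e <- runif(2, 0, 10)
    ranked_from_errors(e[1], e[2])
  })
  tk <- topk_summary(ranked)
  expect_equal(tk$rank1[tk$group == "C2"], 0.5, tolerance = 0.05)
})

test_that("confusion counts honour the retention rule and partition", {
  ranked <- list(ranked_from_errors(2, c(1, 5)))
  cc <- classify_at_threshold(ranked, 3)
  expect_equal(cc[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 1L, tn = 1L, fn = 0L))
  cc100 <- classify_at_threshold(ranked, 100)
  expect_equal(cc100$fn + cc100$tn, 0L)
  set.seed(9)
  ranked <- lapply(1:50, function(i)
    ranked_from_errors(runif(1, 0, 10), runif(sample(0:4, 1), 0, 10)))
  total <- sum(vapply(ranked, attr, integer(1), "n_candidates"))
  for (t in seq(0, 12, length.out = 25)) {
    cc <- classify_at_threshold(ranked, t)
    expect_equal(cc$tp + cc$fn, 50L)
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, total)
  }
})

test_that("ROC sweeps 0-100% and integrates to sane areas", {
  perfect <- lapply(1:30, function(i) ranked_from_errors(0, 50))
  roc <- roc_curve(perfect)
  expect_equal(roc$thresholds, 0:100)
  expect_equal(roc$auc, 1)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_equal(c(roc$tpr[1], roc$fpr[1]), c(1, 0))  # all true at threshold 0
  expect_equal(c(roc$tpr[101], roc$fpr[101]), c(1, 1))
  expect_error(roc_curve(list(ranked_from_errors(1, numeric(0)))), "no PIMs")
})

test_that("same-distribution errors give chance-level AUC", {
  set.seed(10)
  ranked <- lapply(1:2000, function(i)
    ranked_from_errors(runif(1, 0, 30), runif(1, 0, 30)))
  expect_equal(roc_curve(ranked)$auc, 0.5, tolerance = 0.05)
})

test_that("AUC equals the Mann-Whitney probability up to discretisation", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(15:40, 1)
    true_err <- round(runif(n, 0, 20), 0)   # integer grid: no discretisation gap
    pim_err <- round(runif(n, 0, 25), 0)
    ranked <- lapply(seq_len(n), function(i)
      ranked_from_errors(true_err[i], pim_err[i]))
    roc <- roc_curve(ranked)
    u <- mean(outer(true_err, pim_err, "<")) +
      0.5 * mean(outer(true_err, pim_err, "=="))
    expect_equal(roc$auc, u, tolerance = 0.02)
  }
})
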