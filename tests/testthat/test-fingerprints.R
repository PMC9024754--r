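test_that("fingerprints are deterministic and spelling-invariant", {
  cfg <- fingerprint_config("ecfp4", 1024)
  a <- compute_fingerprint("CCO", cfg)
  b <- compute_fingerprint("OCC", cfg)
  expect_identical(as.integer(a), as.integer(b))
  expect_identical(as.integer(a), as.integer(compute_fingerprint("CCO", cfg)))
})

test_that("every class yields its configured width with at least one bit", {
  for (cls in c("ecfp2", "ecfp4", "layered", "path_fp2", "maccs",
                "pubchem_like")) {
    cfg <- fingerprint_config(cls)
    fp <- compute_fingerprint("CC(O)C(N)C", cfg)
    expect_length(fp, cfg$n_bits)
    expect_gt(sum(fp), 0)
  }
  expect_gt(sum(compute_fingerprint("C", fingerprint_config("ecfp2"))), 0)
})

test_that("derivatization changes the circular fingerprint", {
  cfg <- fingerprint_config("ecfp4")
  expect_false(identical(
    as.integer(compute_fingerprint("CCO", cfg)),
    as.integer(compute_fingerprint("CCO[Si](C)(C)C", cfg))))
})

test_that("hashed classes validate n_bits; configs must match", {
  expect_error(fingerprint_config("ecfp4", 1000), "512, 1024, 2048")
  a <- compute_fingerprint("CCO", fingerprint_config("ecfp4", 1024))
  b <- compute_fingerprint("CCO", fingerprint_config("ecfp4", 2048))
  expect_error(tanimoto(a, b), "do not match|lengths differ")
})

test_that("tanimoto matches its set-arithmetic definition", {
  a <- integer(8); a[c(1, 2)] <- 1L
  b <- integer(8); b[c(2, 3)] <- 1L
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(a, a), 1)
  d <- integer(8); d[5:6] <- 1L
  expect_equal(tanimoto(a, d), 0)
  # all-zero conventions
  z <- integer(8)
  expect_equal(tanimoto(z, z), 1)
  expect_equal(tanimoto(z, a), 0)
})

test_that("tanimoto equals the brute-force oracle on 1000 random pairs", {
  set.seed(7)
  for (i in 1:1000) {
    a <- random_bits(); b <- random_bits()
    ia <- which(a == 1L); ib <- which(b == 1L)
    un <- length(union(ia, ib))
    oracle <- if (un == 0) 1 else length(intersect(ia, ib)) / un
    expect_identical(tanimoto(a, b), oracle)
    expect_identical(tanimoto(b, a), tanimoto(a, b))  # symmetry
  }
})

test_that("tanimoto_matrix agrees with the scalar version", {
  set.seed(11)
  A <- matrix(as.integer(runif(10 * 32) < 0.4), 10)
  B <- matrix(as.integer(runif(6 * 32) < 0.4), 6)
  M <- tanimoto_matrix(A, B)
  for (i in 1:10) for (j in 1:6)
    expect_equal(M[i, j], tanimoto(A[i, ], B[j, ]))
})

test_that("max similarity to a pool matches an exhaustive loop", {
  set.seed(3)
  pool <- matrix(as.integer(runif(50 * 64) < 0.3), 50)
  fp <- random_bits()
  res <- max_similarity_to_set(fp, pool)
  brute <- vapply(seq_len(50), function(i) tanimoto(fp, pool[i, ]),
                  numeric(1))
  expect_equal(res$score, max(brute))
  expect_identical(res$index, which.max(brute))
  # membership gives exactly 1 at the member's index
  res2 <- max_similarity_to_set(pool[17, ], pool)
  expect_equal(res2$score, 1)
  expect_identical(res2$index, 17L)
  expect_error(max_similarity_to_set(fp, pool[0, , drop = FALSE]),
               "empty")
})

test_that("generated bits agree with the in-process OpenBabel oracle", {
  smi <- c("CCO", "CC(O)C(N)C", "CC(C)C(S)CC(O[Si](C)(C)C)C(N)C", "C")
  mols <- tmsri:::parse_molecules(smi)
  for (nm in c("ECFP4", "ECFP2", "FP2")) {
    oracle <- ChemmineOB::fingerprint_OB(mols, nm)
    mine <- tmsri:::ob_fingerprints(smi, nm)
    for (i in seq_along(smi))
      expect_identical(which(mine[i, ] == 1L), which(oracle[i, ] != 0),
                       label = paste(nm, smi[i]))
  }
})

test_that("hex export encodes the bit vector faithfully", {
  fp <- matrix(c(1L, 0L, 0L, 1L, 1L, 1L, 1L, 1L), nrow = 1)
  expect_identical(unname(fingerprint_hex(fp)), "9f")
})
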