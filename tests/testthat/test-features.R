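test_that("sigmoid scaling matches its closed form and symmetry", {
  expect_equal(sigmoid_scale(0), 0.5)
  expect_equal(sigmoid_scale(log(3)), 0.75)
  a <- seq(-5, 5, by = 0.37)
  expect_equal(sigmoid_scale(a), 1 - sigmoid_scale(-a))
  expect_true(all(sigmoid_scale(a) > 0 & sigmoid_scale(a) < 1))
})

test_that("pssm_feature averages sigmoid-scaled scores per column", {
  z <- new_pssm("z", "ACDEF", matrix(0, 5, 20))
  expect_equal(unname(pssm_feature(z)), rep(0.5, 20))

  two <- new_pssm("t", "AC", rbind(rep(0, 20), rep(log(3), 20)))
  expect_equal(unname(pssm_feature(two)), rep(0.625, 20))  # (0.5 + 0.75)/2

  p <- random_pssm(L = 17, seed = 3)
  f <- pssm_feature(p)
  expect_length(f, 20L)
  expect_true(all(f > 0 & f < 1))
  # invariant to permuting positions
  perm <- new_pssm(p$protein_id,
                   paste(sample(strsplit(p$residues, "")[[1]]), collapse = ""),
                   p$scores[sample(nrow(p$scores)), ])
  expect_equal(pssm_feature(perm), f)
})

test_that("tripeptide composition counts overlapping windows over the K^3 grid", {
  v <- tripeptide_composition(rep(0L, 4), K = 7)
  expect_length(v, 343L)
  expect_equal(unname(v["0-0-0"]), 1)
  expect_equal(sum(v != 0), 1L)

  v2 <- tripeptide_composition(c(0L, 1L, 0L, 1L), K = 2)
  expect_equal(unname(v2[c("0-1-0", "1-0-1")]), c(0.5, 0.5))
  expect_equal(sum(v2), 1)

  expect_length(tripeptide_labels(20), 8000L)  # raw amino-acid tripeptide space
  expect_error(tripeptide_composition(c(0L, 1L), K = 2), "fewer than 3")
  expect_error(tripeptide_composition(c(0L, 5L, 1L), K = 2), "out of range")
})

test_that("tripeptide composition equals the brute-force dictionary oracle", {
  set.seed(42)
  for (rep_i in 1:100) {
    K <- sample(2:8, 1)
    L <- sample(3:40, 1)
    reduced <- sample(0:(K - 1), L, replace = TRUE)
    fast <- tripeptide_composition(reduced, K)
    expect_equal(fast, brute_force_tripeptides(reduced, K))
    expect_equal(sum(fast), 1, tolerance = 1e-9)
  }
})

test_that("assemble_rtcp concatenates RTC then PSSM block, checking ids", {
  ab <- canonical_alphabets()$ST_CP
  rtc <- tripeptide_composition(reduce_sequence(random_aa_seq(50, 1), ab), 8)
  pf <- pssm_feature(random_pssm("p1", L = 50, seed = 2))
  v <- assemble_rtcp(rtc, pf)
  expect_length(v, 532L)                     # 8^3 + 20
  expect_identical(names(v), c(names(rtc), names(pf)))
  expect_error(assemble_rtcp(rtc, pf, protein_id = "a", pssm_protein_id = "b"),
               "mismatch")
  expect_error(assemble_rtcp(rtc, pf[1:10]), "length 20")
})

test_that("rtcp length is K^3 + 20 for every canonical alphabet", {
  pf <- pssm_feature(random_pssm(L = 30, seed = 5))
  for (a in canonical_alphabets()) {
    K <- alphabet_size(a)
    rtc <- tripeptide_composition(reduce_sequence(random_aa_seq(60, K), a), K)
    expect_length(assemble_rtcp(rtc, pf), K^3 + 20L)
  }
})

test_that("amino_acid_composition returns length-20 frequencies summing to 1", {
  v <- amino_acid_composition("AAAA")
  expect_length(v, 20L)
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)
  v2 <- amino_acid_composition("HQVHQV")
  expect_equal(unname(v2[c("H", "Q", "V")]), rep(1 / 3, 3))
  expect_error(suppressWarnings(amino_acid_composition("XX")), "empty")
})

test_that("extract_features builds one row per protein with carried metadata", {
  d <- tibble::tibble(id = c("a", "b", "c"),
                      seq = vapply(1:3, function(i) random_aa_seq(30, i), ""),
                      label = c(0L, 1L, 0L))
  ab <- canonical_alphabets()$ST_SS
  f1 <- extract_features(d, ab)
  expect_identical(nrow(f1), 3L)
  expect_length(feature_columns(f1), 343L)
  expect_identical(f1$label, d$label)

  pssms <- purrr::map(seq_len(3), function(i)
    new_pssm(d$id[i], d$seq[i], matrix(round(rnorm(30 * 20, 0, 2)), 30, 20)))
  names(pssms) <- d$id
  f2 <- extract_features(d, ab, pssms)
  expect_length(feature_columns(f2), 363L)

  expect_error(extract_features(d, ab, pssms[1:2]), "no PSSM")
  expect_warning(f3 <- extract_features(d, ab, pssms[1:2],
                                        on_missing_pssm = "skip"), "skipped")
  expect_identical(nrow(f3), 2L)
})

test_that("PCA reducer projects onto deterministic principal axes", {
  # points on the line y = x: first component is (1,1)/sqrt(2)
  t <- seq(-3, 3, length.out = 40)
  X <- cbind(t, t)
  colnames(X) <- c("pc_in1", "pc_in2")  # arbitrary names; matrix path
  r <- fit_reducer(X, d_out = 1)
  expect_equal(abs(as.numeric(r$components)), rep(1 / sqrt(2), 2), tolerance = 1e-8)
  expect_true(all(r$components > 0))  # sign fixed positive

  # data in an exact 3-dim subspace reconstructs losslessly
  set.seed(9)
  B <- matrix(rnorm(30), 10, 3)
  Z <- matrix(rnorm(60), 20, 3)
  X2 <- Z %*% t(B)
  r2 <- fit_reducer(X2, d_out = 3)
  proj <- apply_reducer(r2, X2)
  recon <- sweep(proj %*% r2$components, 2, r2$mean, "+")
  expect_equal(recon, X2, tolerance = 1e-8, ignore_attr = TRUE)
  # pairwise distances preserved
  expect_equal(as.matrix(dist(proj)), as.matrix(dist(X2)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("reducer honors dimension bounds and default width 80", {
  set.seed(2)
  X <- matrix(rnorm(120 * 400), 120, 400)
  r <- fit_reducer(X)
  expect_identical(r$d_out, 80L)
  expect_identical(ncol(apply_reducer(r, X)), 80L)
  expect_error(fit_reducer(X[1:10, ], d_out = 80), "exceeds")
  expect_error(apply_reducer(r, X[, 1:30]), "feature columns")
  # orthonormal rows
  G <- r$components %*% t(r$components)
  expect_equal(G, diag(80), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("reducer tidiers report the variance spectrum", {
  set.seed(4)
  X <- matrix(rnorm(50 * 12), 50, 12)
  r <- fit_reducer(X, d_out = 5)
  td <- generics::tidy(r)
  expect_identical(nrow(td), 5L)
  expect_true(all(diff(td$sdev) <= 1e-12))
  g <- generics::glance(r)
  expect_identical(g$d_out, 5L)
  expect_lt(g$var_retained, 1)
})
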