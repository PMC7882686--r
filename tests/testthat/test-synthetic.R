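test_that("generation is deterministic given the seed", {
  spec <- synthetic_spec(n_per_class = 4, length_range = c(10L, 30L), seed = 13)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$pssms, d2$pssms)
  d3 <- generate_dataset(synthetic_spec(n_per_class = 4,
                                        length_range = c(10L, 30L), seed = 14))
  expect_false(identical(d1$sequences$seq, d3$sequences$seq))
})

test_that("generated records respect the spec fields", {
  spec <- synthetic_spec(n_per_class = 5, length_range = c(12L, 20L),
                         alphabet = canonical_alphabets()$ST_CP, seed = 3)
  d <- generate_dataset(spec)
  expect_identical(nrow(d$sequences), 10L)
  expect_identical(d$sequences$label, rep(c(0L, 1L), each = 5))
  lens <- nchar(d$sequences$seq)
  expect_true(all(lens >= 12 & lens <= 20))
  for (i in seq_len(10)) {
    p <- d$pssms[[d$sequences$id[i]]]
    expect_identical(p$residues, d$sequences$seq[i])
    expect_identical(nrow(p$scores), lens[i])
  }
  # one-record-per-class edge case
  tiny <- generate_dataset(synthetic_spec(n_per_class = 1, seed = 5))
  expect_identical(nrow(tiny$sequences), 2L)
})

test_that("invalid spec fields are rejected", {
  expect_error(synthetic_spec(n_per_class = 0), "n_per_class")
  expect_error(synthetic_spec(length_range = c(2L, 10L)), "min >= 3")
  expect_error(synthetic_spec(signal_strength = 1.5), "signal_strength")
})

test_that("class-1 PSSM columns carry the mean shift", {
  d <- generate_dataset(synthetic_spec(n_per_class = 30,
                                       length_range = c(80L, 120L),
                                       signal_strength = 0, pssm_shift = 2,
                                       seed = 21))
  mean_by_class <- vapply(c(0L, 1L), function(cl) {
    ids <- d$sequences$id[d$sequences$label == cl]
    mean(vapply(d$pssms[ids], function(p) mean(p$scores), numeric(1)))
  }, numeric(1))
  # 5 of 20 columns shifted by +2 => overall mean shift 0.5
  expect_equal(mean_by_class[2] - mean_by_class[1], 0.5, tolerance = 0.1)
})

test_that("fixtures round-trip losslessly through the readers", {
  dir <- withr::local_tempdir()
  d <- generate_dataset(synthetic_spec(n_per_class = 3,
                                       length_range = c(10L, 25L), seed = 8))
  manifest <- write_fixtures(d, dir)
  expect_true(all(file.exists(manifest$file)))

  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  expect_identical(seqs$id, d$sequences$id)
  expect_identical(seqs$seq, d$sequences$seq)
  labs <- read_labels(file.path(dir, "labels.tsv"))
  expect_identical(labs$label, d$sequences$label)
  pssms <- read_pssm_dir(dir)
  for (id in d$sequences$id) {
    expect_identical(pssms[[id]]$residues, d$pssms[[id]]$residues)
    expect_equal(pssms[[id]]$scores, d$pssms[[id]]$scores, ignore_attr = TRUE)
  }
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(mf$seed, 8L)
  expect_match(mf$spec_hash, "^[0-9a-f]+$")

  # byte-identical files from the same seed
  dir2 <- withr::local_tempdir()
  write_fixtures(generate_dataset(d$spec), dir2)
  f1 <- readLines(file.path(dir, "sequences.fasta"))
  expect_identical(f1, readLines(file.path(dir2, "sequences.fasta")))
  p1 <- readLines(file.path(dir, paste0(d$sequences$id[1], ".pssm")))
  expect_identical(p1, readLines(file.path(dir2, paste0(d$sequences$id[1], ".pssm"))))
})

test_that("cross-validated accuracy rises with signal strength", {
  acc_at <- function(signal, seed) {
    feats <- synth_features(n_per_class = 40, signal = signal, shift = 0,
                            seed = seed, length_range = c(40L, 100L))
    generics::glance(cross_validate(feats, classifier = "svm", k = 4,
                                    d_out = 20, seed = seed))$acc
  }
  levels <- c(0, 0.25, 0.5)
  mean_acc <- vapply(levels, function(s) {
    mean(vapply(1:3, function(sd) acc_at(s, 300 + sd), numeric(1)))
  }, numeric(1))
  # allow sampling noise at the low end, require a clear overall rise
  expect_true(mean_acc[3] > mean_acc[1] + 0.1)
  expect_true(mean_acc[2] >= mean_acc[1] - 0.05)
  expect_true(mean_acc[3] >= mean_acc[2] - 0.05)
})
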