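test_that("profiles built from identical rows concentrate on the consensus", {
  h <- build_profile(toy_msa_clean("ACDEF"), "toy")
  expect_equal(h$match_count, 5)
  expect_equal(profile_consensus(h), "ACDEF")
  peak <- vapply(1:5, function(k) max(h$match_em[k, ]), numeric(1))
  expect_true(all(peak > 0.7))
})

test_that("low-occupancy columns become insert states", {
  msa <- aa_alignment(tibble::tibble(
    id = c("a", "b", "c"),
    aligned = c("AC-DE", "AC-DE", "ACWDE"))) # middle column occupancy 1/3
  h <- build_profile(msa, "occ")
  expect_equal(h$match_count, 4)
  msa_bad <- aa_alignment(tibble::tibble(id = c("a", "b", "c"),
                                         aligned = c("A---", "-C--", "---D")))
  expect_error(build_profile(msa_bad, "none"), "occupancy")
})

test_that("emissions and transitions stay normalised after building", {
  for (h in c(list(build_profile(toy_msa_gappy(), "gappy")),
              ref_profiles()[c("DNase1", "DNase2b", "DNase1L2")])) {
    expect_true(all(abs(rowSums(h$match_em) - 1) < 1e-9))
    ks <- seq_len(h$match_count - 1)
    expect_true(all(abs(rowSums(h$trans[ks, c("MM", "MI", "MD"), drop = FALSE]) - 1) < 1e-9))
    expect_true(all(abs(rowSums(h$trans[ks, c("IM", "II"), drop = FALSE]) - 1) < 1e-9))
  }
})

test_that("forward equals the brute-force path sum on small profiles", {
  h_gappy <- build_profile(toy_msa_gappy(), "gappy")
  h_clean <- build_profile(toy_msa_clean("ACDE"), "clean")
  letters4 <- c("A", "C", "D", "E")
  for (h in list(h_gappy, h_clean)) {
    for (len in 1:4) {
      for (s in all_strings(letters4, len)) {
        fw <- forward_score(h, s)
        or <- oracle_hmm_score(h, s, "sum")
        expect_equal(fw, or, tolerance = 1e-9, info = paste(h$label, s))
      }
    }
  }
  # spot checks at lengths 5 and 6 (full sweeps run in the acceptance suite)
  set.seed(3)
  for (s in replicate(40, paste(sample(letters4, sample(5:6, 1), TRUE),
                                collapse = ""))) {
    expect_equal(forward_score(h_gappy, s),
                 oracle_hmm_score(h_gappy, s, "sum"), tolerance = 1e-9)
  }
})

test_that("Viterbi never exceeds forward and matches the max-path oracle", {
  h <- build_profile(toy_msa_gappy(), "gappy")
  letters4 <- c("A", "C", "D", "E")
  set.seed(17)
  for (s in replicate(60, paste(sample(letters4, sample(1:6, 1), TRUE),
                                collapse = ""))) {
    v <- viterbi_align(h, s)$score
    f <- forward_score(h, s)
    expect_lte(v, f + 1e-9)
    expect_equal(v, oracle_hmm_score(h, s, "max"), tolerance = 1e-9)
  }
  # real profiles, longer sequences
  profs <- ref_profiles()
  withr::with_seed(7, {
    for (g in c("DNase1", "DNase2")) {
      s <- sample_sequence(profs[[g]])$sequence
      expect_lte(viterbi_align(profs[[g]], s)$score + 1e-6,
                 forward_score(profs[[g]], s) + 1e-6)
    }
  })
})

test_that("Viterbi paths expose matches, deletions and insertions", {
  h <- build_profile(toy_msa_clean("ACDEF"), "toy")
  all_match <- viterbi_align(h, "ACDEF")$path
  expect_equal(all_match$state, rep("M", 5))
  expect_equal(all_match$match_state, 1:5)

  del <- viterbi_align(h, "ACEF")$path
  expect_equal(sum(del$state == "D"), 1)
  expect_equal(del$match_state[del$state == "D"], 3)

  ins <- viterbi_align(h, "ACDWEF")$path
  expect_equal(sum(ins$state == "I"), 1)
  expect_equal(sum(ins$state == "M"), 5)

  # a length-1 sequence against a single-match-state profile: forward sums
  # over a superset of paths, so it cannot be below Viterbi
  h1 <- build_profile(toy_msa_clean("A", n = 3), "one")
  expect_gte(forward_score(h1, "A"), viterbi_align(h1, "A")$score - 1e-12)
})

test_that("Gumbel calibration is deterministic and location-equivariant", {
  h <- build_profile(toy_msa_clean("ACDEFGHIKL"), "cal")
  c1 <- calibrate_profile(h, n_samples = 120, seed = 5)
  c2 <- calibrate_profile(h, n_samples = 120, seed = 5)
  expect_identical(c(c1$mu, c1$lambda), c(c2$mu, c2$lambda))
  expect_error(calibrate_profile(h, n_samples = 50, seed = 1), "100")

  set.seed(2)
  x <- rnorm(300)
  f0 <- dnaserep:::fit_gumbel(x)
  f1 <- dnaserep:::fit_gumbel(x + 3.5)
  expect_equal(unname(f1["mu"] - f0["mu"]), 3.5, tolerance = 1e-6)
  expect_equal(unname(f1["lambda"]), unname(f0["lambda"]), tolerance = 1e-6)
  expect_error(dnaserep:::fit_gumbel(rep(1, 200)), "degenerate")
})

test_that("E-values decrease monotonically in the bit score", {
  h <- ref_profiles()$DNase1
  scores <- seq(-50, 50, by = 10)
  ev <- profile_evalue(h, scores, dbsize = 1000)
  expect_true(all(diff(ev) < 0))
  expect_true(all(ev >= 0))
})

test_that("true members reach the assignment threshold, decoys never do", {
  profs <- ref_profiles()
  members <- withr::with_seed(23, purrr::map(1:20, function(i) {
    g <- dnase_orthogroups()[(i - 1) %% 10 + 1]
    list(g = g, s = sample_sequence(profs[[g]])$sequence)
  }))
  ev <- vapply(members, function(m) {
    profile_evalue(profs[[m$g]], forward_score(profs[[m$g]], m$s), 1000)
  }, numeric(1))
  expect_gte(mean(ev <= 1e-20), 0.95)

  proteome <- tibble::tibble(
    id = paste0("m", seq_along(members)),
    sequence = vapply(members, `[[`, "", "s"))
  scan <- scan_proteome(proteome, profs, dbsize = 1000)
  expect_equal(scan$label, vapply(members, `[[`, "", "g"))

  decoys <- withr::with_seed(29, tibble::tibble(
    id = paste0("d", 1:30),
    sequence = vapply(proteome$sequence[sample(20, 30, TRUE)], function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, "", USE.NAMES = FALSE)))
  dscan <- scan_proteome(decoys, profs, dbsize = 1000)
  expect_true(all(is.na(dscan$label)))
})

test_that("a repertoire of six human-like DNases splits four to two", {
  profs <- ref_profiles()
  human_groups <- c("DNase1", "DNase1L1", "DNase1L2", "DNase1L3",
                    "DNase2", "DNase2b")
  proteome <- withr::with_seed(41, tibble::tibble(
    id = paste0("Hs_", human_groups), taxon = "Homo_sapiens",
    sequence = vapply(human_groups, function(g) {
      sample_sequence(profs[[g]])$sequence
    }, "", USE.NAMES = FALSE)))
  scan <- scan_proteome(proteome, profs)
  expect_equal(sum(scan$label %in% c("DNase2", "DNase2b")), 2)
  expect_equal(sum(startsWith(scan$label, "DNase1")), 4)
})

test_that("empty proteomes scan to empty results", {
  empty <- tibble::tibble(id = character(), sequence = character())
  res <- scan_proteome(empty, ref_profiles())
  expect_equal(nrow(res), 0)
  expect_named(res, c("id", "taxon", "label", "bitscore", "evalue"))
})

test_that("scanning requires calibrated profiles", {
  h <- build_profile(toy_msa_clean("ACDEF"), "raw")
  expect_error(scan_proteome(tibble::tibble(id = "x", sequence = "ACDEF"),
                             list(raw = h)), "uncalibrated")
})

test_that("profile sampling is seed-deterministic and score-coherent", {
  h <- ref_profiles()$DNase1L3
  s1 <- sample_sequence(h, seed = 4)
  s2 <- sample_sequence(h, seed = 4)
  s3 <- sample_sequence(h, seed = 5)
  expect_identical(s1$sequence, s2$sequence)
  expect_false(identical(s1$sequence, s3$sequence))

  # a near-deterministic profile with no indel mass reproduces its consensus
  hd <- h
  hd$match_em <- matrix(0, h$match_count, 20, dimnames = list(NULL, dnaserep:::AA20))
  cons <- strsplit(profile_consensus(h), "")[[1]]
  hd$match_em[cbind(seq_along(cons), match(cons, dnaserep:::AA20))] <- 1
  hd$trans[, "MM"] <- 1
  hd$trans[, c("MI", "MD")] <- 0
  expect_equal(sample_sequence(hd, seed = 1)$sequence, profile_consensus(h))

  samples <- withr::with_seed(6, replicate(50, sample_sequence(h)$sequence))
  shuffles <- withr::with_seed(8, vapply(samples, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE))
  ms <- mean(vapply(samples, function(s) forward_score(h, s), numeric(1)))
  mh <- mean(vapply(shuffles, function(s) forward_score(h, s), numeric(1)))
  expect_gt(ms, mh)
})

test_that("profile serialization round-trips byte-identically", {
  h <- ref_profiles()$DNase1
  p1 <- withr::local_tempfile(fileext = ".hmm")
  p2 <- withr::local_tempfile(fileext = ".hmm")
  write_profile(h, p1)
  h2 <- read_profile(p1)
  write_profile(h2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(h2$label, h$label)
  expect_equal(h2$match_count, h$match_count)
  expect_equal(h2$reference_map, h$reference_map)
  expect_equal(h2$mu, h$mu, tolerance = 1e-5)
  # scores from the reread profile match at the serialized precision
  s <- withr::with_seed(3, sample_sequence(h)$sequence)
  expect_equal(forward_score(h2, s), forward_score(h, s), tolerance = 1e-3)
})
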