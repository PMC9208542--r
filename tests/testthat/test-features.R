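test_that("reference positions map through the Viterbi alignment", {
  profs <- ref_profiles()
  h1 <- profs$DNase1
  cons <- profile_consensus(h1)
  mapping <- map_reference_positions(h1, cons)
  expect_setequal(names(mapping), names(h1$reference_map))
  expect_equal(unname(mapping[names(h1$reference_map)]),
               unname(h1$reference_map)) # consensus: index = match order

  # deleting the loop that carries C101-C104 removes exactly those labels,
  # the situation of a DNase1L2-type sequence scored on the DNase1 profile
  loop <- 95:109
  no_loop <- paste(strsplit(cons, "")[[1]][-loop], collapse = "")
  mapping2 <- map_reference_positions(h1, no_loop)
  expect_false(any(c("C101", "C104") %in% names(mapping2)))
  expect_true(all(c("C173", "C209") %in% names(mapping2)))

  expect_error(map_reference_positions(build_profile(toy_msa_clean("ACDE"),
                                                     "bare"), "ACDE"),
               "reference_map")
})

test_that("cysteine pairs are detected only when both residues are cysteine", {
  profs <- ref_profiles()
  cases <- list(
    DNase1 = c("C101-C104", "C173-C209"),
    DNase1L3 = c("C4-C32", "C173-C209"),
    DNase1L2 = "C173-C209",
    DNase1L1 = c("C4-C32", "C173-C209"))
  for (g in names(cases)) {
    s <- member_of(g)
    mapping <- map_reference_positions(profs[[g]], s)
    pairs <- detect_cys_pairs(mapping, s)
    expect_setequal(intersect(pairs, dnaserep:::DNASE1_PAIRS), cases[[g]])
    # no hallucinated pairs: every reported pair is literally C at both ends
    chars <- strsplit(s, "")[[1]]
    for (p in pairs) {
      members <- cys_pair_definitions()[[p]]
      expect_true(all(chars[mapping[members]] == "C"))
    }
  }
  no_cys <- gsub("C", "S", member_of("DNase1"))
  mapping <- map_reference_positions(profs$DNase1, no_cys)
  expect_length(detect_cys_pairs(mapping, no_cys), 0)
})

test_that("the C-terminal cascade is total, deterministic and as forced", {
  pad <- strrep("QNT", 10)
  basic <- classify_cterminus(paste0(pad, "KKSKRSKKAGRK"))
  expect_equal(basic$cterm_class, "BASIC")
  expect_gte(basic$basic_charge, 4)

  gpi <- classify_cterminus(paste0(pad, "GSAASGSALLLLVVVAAL"))
  expect_equal(gpi$cterm_class, "GPI")
  expect_false(is.na(gpi$omega_site))

  el <- classify_cterminus(paste0(pad, "QSTNDSQSTNEL"))
  expect_equal(el$cterm_class, "EL")

  smb <- classify_cterminus(paste0(pad, "CSSCDCNNCKCESC"))
  expect_equal(smb$cterm_class, "SMB")

  none <- classify_cterminus(paste0(pad, "QTGSDNSATGQS"))
  expect_equal(none$cterm_class, "NONE")

  short <- classify_cterminus("MKWACDEFGHIKL")
  expect_equal(short$cterm_class, "NONE")
  expect_true(short$cterm_warning)

  # exactly one class per sequence, stable across calls
  set.seed(12)
  for (rep in 1:20) {
    s <- random_protein(60)
    a <- classify_cterminus(s); b <- classify_cterminus(s)
    expect_identical(a, b)
    expect_true(a$cterm_class %in% c("GPI", "BASIC", "SMB", "EL", "NONE"))
  }
})

test_that("the signal-peptide heuristic follows its hydropathy contract", {
  expect_true(detect_signal_peptide(
    paste0("MKKLLLLLLLLAVA", strrep("DQNSTE", 8))))
  expect_false(detect_signal_peptide(strrep("DE", 30)))
  # hydrophobic window too late / behind a negative segment does not count
  expect_false(detect_signal_peptide(
    paste0("MDEDESDETQ", strrep("QN", 15), "LLLLLLLL", strrep("S", 20))))
})

test_that("PLD HxK motifs are counted at the mapped triads", {
  profs <- ref_profiles()
  s <- member_of("DNase2b")
  mapping <- map_reference_positions(profs$DNase2b, s)
  expect_equal(detect_pld_hxk(s, mapping), 2L)

  chars <- strsplit(s, "")[[1]]
  chars[mapping[["H1"]]] <- "A"
  mutated <- paste(chars, collapse = "")
  mapping2 <- map_reference_positions(profs$DNase2b, mutated)
  expect_equal(detect_pld_hxk(mutated, mapping2), 1L)

  # a PLD2-only truncation (short-isoform analogue) keeps a single motif
  start <- mapping[["K1"]] + 5
  trunc <- substr(s, start, nchar(s))
  mapping3 <- map_reference_positions(profs$DNase2b, trunc)
  expect_equal(detect_pld_hxk(trunc, mapping3), 1L)
})

test_that("every expectation row is satisfied by its own synthetic member", {
  profs <- ref_profiles()
  for (g in dnase_orthogroups()) {
    proteome <- tibble::tibble(id = g, taxon = "t", sequence = member_of(g))
    calls <- classify_sequences(proteome, profs, dbsize = 100)
    expect_equal(calls$label, g)
    expect_equal(calls$flags[[1]], character(0), label = g)
  }
})

test_that("feature mismatches flag without rejecting the call", {
  profs <- ref_profiles()
  imp <- dnaserep:::implant_table()
  # a DNase1L4 with an (unexpected) signal peptide
  core <- withr::with_seed(51, dnaserep:::implant_core(profs$DNase1L4))
  s <- paste0(imp$prefix[imp$label == "DNase1"], core,
              imp$suffix[imp$label == "DNase1L4"])
  calls <- classify_sequences(tibble::tibble(id = "x", taxon = "t",
                                             sequence = s), profs,
                              dbsize = 100)
  expect_equal(calls$label, "DNase1L4")
  expect_true("signal_peptide_unexpected" %in% calls$flags[[1]])

  # a lamprey-style DNase1L3 lacking the basic C-terminal peptide
  core <- withr::with_seed(52, dnaserep:::implant_core(profs$DNase1L3))
  s2 <- paste0(imp$prefix[imp$label == "DNase1L3"], core,
               imp$suffix[imp$label == "DNase1"]) # neutral tail instead
  calls2 <- classify_sequences(tibble::tibble(id = "y", taxon = "t",
                                              sequence = s2), profs,
                               dbsize = 100)
  expect_equal(calls2$label, "DNase1L3")
  expect_true(any(grepl("cterm_expected_BASIC", calls2$flags[[1]])))

  # unassigned records carry the unassigned flag
  calls3 <- classify_sequences(tibble::tibble(id = "z", taxon = "t",
                                              sequence = strrep("ACDEG", 50)),
                               profs, dbsize = 100)
  expect_true(is.na(calls3$label))
  expect_equal(calls3$flags[[1]], "unassigned")
})

test_that("call tables export with the documented columns", {
  b <- ref_bundle()
  calls <- ref_calls()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(tab), nrow(calls))
  expect_true(all(c("id", "taxon", "label", "bitscore", "evalue",
                    "cys_pairs", "cterm_class", "signal_peptide",
                    "pld_hxk", "flags") %in% names(tab)))
})
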