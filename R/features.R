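#' Diagnostic sequence features of DNase proteins
#'
#' The orthogroups carry diagnostic features beyond profile similarity:
#' disulfide-forming cysteine pairs, distinct C-terminal classes (GPI-anchor
#' signal, basic peptide, somatomedin-B cysteine stretch, terminal "EL"),
#' N-terminal signal peptides, and the HxK catalytic motifs of the two
#' phospholipase-D domains of the DNase2 family. These are detected from the
#' Viterbi mapping of reference positions plus simple, configurable sequence
#' heuristics, and then checked against the per-orthogroup expectation table.
#'
#' @name features
NULL

#' The ten DNase orthogroups
#' @return Character vector of orthogroup labels.
#' @export
dnase_orthogroups <- function() {
  c("DNase1", "DNase1L1", "DNase1L1L", "DNase1L2", "DNase1L3",
    "DNase1L4", "DNase1L4-2", "DNase1L5", "DNase2", "DNase2b")
}

#' Known cysteine-pair definitions
#'
#' Pair labels map to the two reference-residue labels carried in a profile's
#' `reference_map`. `C4-C32`, `C101-C104` and `C173-C209` are the DNase1
#' family pairs (human DNase1 numbering); `P1`..`P3` are the DNase2-family
#' pairs and `P4` the extra pair of DNase2b.
#'
#' @return Named list of length-2 character vectors.
#' @export
cys_pair_definitions <- function() {
  list("C4-C32" = c("C4", "C32"),
       "C101-C104" = c("C101", "C104"),
       "C173-C209" = c("C173", "C209"),
       "P1" = c("P1a", "P1b"), "P2" = c("P2a", "P2b"),
       "P3" = c("P3a", "P3b"), "P4" = c("P4a", "P4b"))
}

#' Feature-detection constants
#'
#' All thresholds of the C-terminal cascade and the signal-peptide heuristic,
#' exposed so they can be tuned. Defaults: GPI omega site = small residue
#' (S/G/A/N/D/C) within the last `omega_window` residues followed by a
#' 6-residue spacer and a hydrophobic tail (>= `min_tail` residues, mean
#' Kyte-Doolittle >= `tail_hydropathy`); basic peptide = net charge of the
#' last `basic_window` residues >= `basic_min_charge` (K/R = +1, D/E = -1,
#' H = 0); SMB = >= `smb_min_cys` cysteines in the last `smb_window`
#' residues; signal peptide = an 8-residue window within the first 35
#' residues with mean hydropathy >= `signal_hydropathy` preceded by a
#' non-negatively charged segment.
#'
#' @param omega_window,spacer,min_tail,tail_hydropathy GPI parameters.
#' @param omega_residues Residues allowed at the omega site.
#' @param basic_window,basic_min_charge Basic-peptide parameters.
#' @param smb_window,smb_min_cys SMB parameters.
#' @param signal_region,signal_window,signal_hydropathy Signal-peptide
#'   parameters.
#' @return Named list of constants.
#' @export
feature_params <- function(omega_window = 40, spacer = 6, min_tail = 8,
                           tail_hydropathy = 1.0,
                           omega_residues = c("S", "G", "A", "N", "D", "C"),
                           basic_window = 12, basic_min_charge = 4,
                           smb_window = 60, smb_min_cys = 6,
                           signal_region = 35, signal_window = 8,
                           signal_hydropathy = 1.6) {
  as.list(environment())
}

#' Map reference residue labels onto a sequence
#'
#' Runs the Viterbi alignment of `seq` against `hmm` and returns, for every
#' reference label whose match state is visited by a match step, the aligned
#' 1-based sequence position. Labels whose match state is deleted are absent
#' from the result.
#'
#' @param hmm A `profile_hmm` with a non-empty `reference_map`.
#' @param seq Sequence string or single-row tibble.
#' @return Named integer vector (reference label -> sequence index).
#' @export
map_reference_positions <- function(hmm, seq) {
  if (length(hmm$reference_map) == 0) {
    stop("profile has no reference_map", call. = FALSE)
  }
  vit <- viterbi_align(hmm, seq)
  if (nrow(vit$path) == 0) stop("empty Viterbi path", call. = FALSE)
  m <- dplyr::filter(vit$path, .data$state == "M")
  pos <- setNames(m$residue, m$match_state)
  hit <- as.character(hmm$reference_map) %in% names(pos)
  setNames(as.integer(pos[as.character(hmm$reference_map[hit])]),
           names(hmm$reference_map)[hit])
}

#' Detect conserved cysteine pairs
#'
#' A pair is reported iff both member positions are mapped and both mapped
#' residues are literally cysteine.
#'
#' @param mapping Named positions from [map_reference_positions()].
#' @param seq Sequence string or single-row tibble.
#' @param pairs Pair definitions (default [cys_pair_definitions()]).
#' @return Character vector of detected pair labels (possibly empty).
#' @export
detect_cys_pairs <- function(mapping, seq, pairs = cys_pair_definitions()) {
  chars <- seq_chars(seq)
  hit <- vapply(pairs, function(p) {
    all(p %in% names(mapping)) && all(chars[mapping[p]] == "C")
  }, logical(1))
  names(pairs)[hit]
}

#' Classify the C-terminus of a protein
#'
#' Decision cascade (most specific signal first): GPI if an omega-site
#' pattern is found; else BASIC if the terminal window is sufficiently
#' positively charged; else SMB if the terminal region is cysteine-rich;
#' else EL if the final two residues are exactly "EL"; else NONE. For the
#' GPI search, candidate omega positions are scanned from the C-terminus
#' inwards and the first valid one wins. Sequences shorter than 30 residues
#' return NONE with a warning flag.
#'
#' @param seq Sequence string or single-row tibble.
#' @param params Constants from [feature_params()].
#' @return One-row tibble: `cterm_class`, `omega_site` (1-based index or
#'   `NA`), `basic_charge`, `cterm_warning`.
#' @export
classify_cterminus <- function(seq, params = feature_params()) {
  chars <- seq_chars(seq)
  n <- length(chars)
  basic_charge <- net_charge(chars[seq(max(1, n - params$basic_window + 1), n)])
  if (n < 30) {
    return(tibble(cterm_class = "NONE", omega_site = NA_integer_,
                  basic_charge = basic_charge, cterm_warning = TRUE))
  }
  # GPI: omega + 6-residue spacer + hydrophobic tail to the terminus
  p_hi <- n - params$spacer - params$min_tail
  p_lo <- max(1, n - params$omega_window + 1)
  omega <- NA_integer_
  if (p_hi >= p_lo) {
    for (p in seq(p_hi, p_lo)) {
      if (!(chars[p] %in% params$omega_residues)) next
      tail <- chars[(p + params$spacer + 1):n]
      if (mean_hydropathy(tail) >= params$tail_hydropathy) { omega <- p; break }
    }
  }
  cls <-
    if (!is.na(omega)) "GPI"
    else if (basic_charge >= params$basic_min_charge) "BASIC"
    else if (sum(chars[seq(max(1, n - params$smb_window + 1), n)] == "C") >=
             params$smb_min_cys) "SMB"
    else if (paste(chars[c(n - 1, n)], collapse = "") == "EL") "EL"
    else "NONE"
  tibble(cterm_class = cls,
         omega_site = if (cls == "GPI") omega else NA_integer_,
         basic_charge = basic_charge, cterm_warning = FALSE)
}

#' Heuristic signal-peptide detection
#'
#' TRUE iff the first `signal_region` residues contain a `signal_window`-long
#' stretch of mean Kyte-Doolittle hydropathy >= `signal_hydropathy` whose
#' preceding segment has non-negative net charge. A stand-in for dedicated
#' signal-peptide predictors; its contract is defined on the synthetic
#' fixtures, not on real proteins.
#'
#' @inheritParams classify_cterminus
#' @return Logical scalar.
#' @export
detect_signal_peptide <- function(seq, params = feature_params()) {
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < 25) return(FALSE)
  w <- params$signal_window
  region_end <- min(params$signal_region, n)
  for (s in seq_len(region_end - w + 1)) {
    window <- chars[s:(s + w - 1)]
    if (mean_hydropathy(window) < params$signal_hydropathy) next
    if (s == 1 || net_charge(chars[seq_len(s - 1)]) >= 0) return(TRUE)
  }
  FALSE
}

#' Count HxK phospholipase-D catalytic motifs
#'
#' Counts, over the two PLD domains, how many catalytic triads carry the
#' H-x-K pattern at the reference-mapped positions (`H1`/`K1`, `H2`/`K2`).
#'
#' @param seq Sequence string or single-row tibble.
#' @param mapping Named positions from [map_reference_positions()].
#' @return Integer in 0..2.
#' @export
detect_pld_hxk <- function(seq, mapping) {
  chars <- seq_chars(seq)
  count <- 0L
  for (d in 1:2) {
    h <- mapping[paste0("H", d)]; k <- mapping[paste0("K", d)]
    if (!is.na(h) && !is.na(k) && length(h) && length(k) &&
        chars[h] == "H" && chars[k] == "K") {
      count <- count + 1L
    }
  }
  count
}

#' Per-orthogroup feature expectations
#'
#' The feature signature each orthogroup is expected to carry: cysteine
#' pairs, signal peptide, C-terminal class, and (for the DNase2 family) the
#' number of intact PLD HxK motifs. `NA` entries are not checked.
#'
#' @return Tibble with columns `label`, `cys_pairs` (list), `signal_peptide`,
#'   `cterm_class`, `pld_hxk`.
#' @export
orthogroup_expectations <- function() {
  tibble(
    label = dnase_orthogroups(),
    cys_pairs = list(
      c("C101-C104", "C173-C209"),      # DNase1
      c("C4-C32", "C173-C209"),         # DNase1L1
      c("C4-C32", "C173-C209"),         # DNase1L1L
      c("C173-C209"),                   # DNase1L2
      c("C4-C32", "C173-C209"),         # DNase1L3
      c("C173-C209"),                   # DNase1L4
      c("C173-C209"),                   # DNase1L4-2
      c("C101-C104", "C173-C209"),      # DNase1L5
      NULL,                             # DNase2 (pairs not checked)
      NULL),                            # DNase2b
    signal_peptide = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                       TRUE, TRUE),
    cterm_class = c("NONE", "GPI", "EL", "NONE", "BASIC", "BASIC", "BASIC",
                    "SMB", NA, NA),
    pld_hxk = c(rep(NA_integer_, 8), 2L, 2L))
}

# family-1 pair labels (used to restrict which pairs count as "unexpected")
DNASE1_PAIRS <- c("C4-C32", "C101-C104", "C173-C209")

compute_flags <- function(label, cys_pairs, signal_peptide, cterm_class,
                          pld_hxk, expectations = orthogroup_expectations()) {
  if (is.na(label)) return("unassigned")
  row <- expectations[expectations$label == label, ]
  if (nrow(row) == 0) return(paste0("unknown_label:", label))
  flags <- character(0)
  exp_pairs <- row$cys_pairs[[1]]
  if (!is.null(exp_pairs)) {
    missing <- setdiff(exp_pairs, cys_pairs)
    extra <- setdiff(intersect(cys_pairs, DNASE1_PAIRS), exp_pairs)
    flags <- c(flags,
               if (length(missing)) paste0("cys_missing:", missing),
               if (length(extra)) paste0("cys_unexpected:", extra))
  }
  if (!is.na(row$signal_peptide) && signal_peptide != row$signal_peptide) {
    flags <- c(flags, if (row$signal_peptide) "signal_peptide_missing"
                      else "signal_peptide_unexpected")
  }
  if (!is.na(row$cterm_class) && cterm_class != row$cterm_class) {
    flags <- c(flags, paste0("cterm_expected_", row$cterm_class,
                             "_got_", cterm_class))
  }
  if (!is.na(row$pld_hxk) && pld_hxk != row$pld_hxk) {
    flags <- c(flags, paste0("pld_hxk_expected_", row$pld_hxk,
                             "_got_", pld_hxk))
  }
  flags
}

#' Consolidate hits and feature evidence into orthogroup calls
#'
#' Joins best-match assignments with feature evidence and computes
#' consistency flags against [orthogroup_expectations()]. Mismatches flag,
#' they never reject a call.
#'
#' @param calls Tibble from [scan_proteome()].
#' @param evidence Tibble with one row per record id: `cys_pairs` (list
#'   column), `signal_peptide`, `cterm_class`, `omega_site`, `basic_charge`,
#'   `pld_hxk`.
#' @return Calls joined with evidence plus a `flags` list column and a
#'   `flagged` logical.
#' @export
consolidate_calls <- function(calls, evidence) {
  out <- dplyr::left_join(calls, evidence, by = "id")
  out$flags <- purrr::pmap(
    list(out$label, out$cys_pairs, out$signal_peptide, out$cterm_class,
         out$pld_hxk),
    function(label, cys, sp, ct, pld) {
      compute_flags(label, cys %||% character(0), isTRUE(sp),
                    ct %||% "NONE", pld %||% 0L)
    })
  out$flagged <- lengths(out$flags) > 0
  out
}

#' Classify a proteome end to end
#'
#' Scans records against the profiles, computes feature evidence for every
#' assigned record using its best-match profile's reference map, and
#' consolidates the result into verified orthogroup calls.
#'
#' @inheritParams scan_proteome
#' @param params Feature constants ([feature_params()]).
#' @return Tibble of consolidated calls (one row per record) with evidence
#'   columns and `flags`.
#' @export
classify_sequences <- function(proteome, profiles, evalue_threshold = 1e-20,
                               dbsize = NULL, params = feature_params()) {
  labels <- vapply(profiles, function(p) p$label, character(1))
  names(profiles) <- labels
  calls <- scan_proteome(proteome, profiles, evalue_threshold, dbsize)
  evidence <- purrr::map(seq_len(nrow(calls)), function(i) {
    s <- proteome$sequence[match(calls$id[i], proteome$id)]
    ct <- classify_cterminus(s, params)
    sp <- detect_signal_peptide(s, params)
    lab <- calls$label[i]
    cys <- character(0); pld <- 0L
    if (!is.na(lab) && length(profiles[[lab]]$reference_map) > 0) {
      mapping <- map_reference_positions(profiles[[lab]], s)
      cys <- detect_cys_pairs(mapping, s)
      pld <- detect_pld_hxk(s, mapping)
    }
    tibble(id = calls$id[i], cys_pairs = list(cys), signal_peptide = sp,
           cterm_class = ct$cterm_class, omega_site = ct$omega_site,
           basic_charge = ct$basic_charge, pld_hxk = pld)
  })
  evidence <- if (length(evidence) == 0) {
    tibble(id = character(), cys_pairs = list(), signal_peptide = logical(),
           cterm_class = character(), omega_site = integer(),
           basic_charge = integer(), pld_hxk = integer())
  } else {
    dplyr::bind_rows(evidence)
  }
  consolidate_calls(calls, evidence)
}

#' Export consolidated calls as TSV
#'
#' Columns: record, taxon, label, bitscore, evalue, cys_pairs (comma-joined),
#' cterm_class, omega_site, basic_charge, signal_peptide, pld_hxk, flags
#' (semicolon-joined).
#'
#' @param calls Tibble from [classify_sequences()].
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  flat <- dplyr::mutate(
    calls,
    cys_pairs = vapply(.data$cys_pairs, paste, "", collapse = ","),
    flags = vapply(.data$flags, paste, "", collapse = ";"))
  cols <- c("id", "taxon", "label", "bitscore", "evalue", "cys_pairs",
            "cterm_class", "omega_site", "basic_charge", "signal_peptide",
            "pld_hxk", "flags")
  readr::write_tsv(flat[, intersect(cols, names(flat))], path)
  invisible(path)
}
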