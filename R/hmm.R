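#' Profile hidden Markov models for orthogroup classification
#'
#' A `profile_hmm` models one orthogroup as a chain of match states with
#' insert and delete states in a Plan7-style topology, in glocal mode: every
#' path enters at the first match state and leaves from the last, and
#' background-emitting flanking insert states absorb N- and C-terminal
#' overhangs. Insert states emit the background distribution, so only match
#' states carry log-odds information.
#'
#' @name profile_hmm
NULL

TRANS_COLS <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

new_profile_hmm <- function(label, match_em, trans, background,
                            insert_em = background, reference_map = integer(),
                            mu = NA_real_, lambda = NA_real_,
                            flank_loop = 0.9, validate = TRUE, tol = 1e-9) {
  L <- nrow(match_em)
  stopifnot(L >= 1, ncol(match_em) == 20, nrow(trans) == L, ncol(trans) == 7)
  colnames(trans) <- TRANS_COLS
  colnames(match_em) <- AA20
  hmm <- structure(
    list(label = label, match_count = L, match_em = match_em,
         insert_em = insert_em, trans = trans, background = background,
         reference_map = reference_map, mu = mu, lambda = lambda,
         flank_loop = flank_loop),
    class = "profile_hmm")
  if (validate) validate_profile_hmm(hmm, tol = tol)
  hmm
}

validate_profile_hmm <- function(hmm, tol = 1e-9) {
  L <- hmm$match_count
  if (any(abs(rowSums(hmm$match_em) - 1) > tol)) {
    stop("match emissions do not sum to 1", call. = FALSE)
  }
  if (abs(sum(hmm$background) - 1) > tol || abs(sum(hmm$insert_em) - 1) > tol) {
    stop("background/insert emissions do not sum to 1", call. = FALSE)
  }
  if (L > 1) {
    ks <- seq_len(L - 1)
    if (any(abs(rowSums(hmm$trans[ks, c("MM", "MI", "MD"), drop = FALSE]) - 1) > tol) ||
        any(abs(rowSums(hmm$trans[ks, c("IM", "II"), drop = FALSE]) - 1) > tol)) {
      stop("transition rows do not sum to 1", call. = FALSE)
    }
    dk <- ks[ks >= 2]
    if (length(dk) > 0 &&
        any(abs(rowSums(hmm$trans[dk, c("DM", "DD"), drop = FALSE]) - 1) > tol)) {
      stop("delete transitions do not sum to 1", call. = FALSE)
    }
  }
  rm <- hmm$reference_map
  if (length(rm) > 0 && (anyDuplicated(rm) || any(rm < 1) || any(rm > L))) {
    stop("reference_map must be injective into 1..match_count", call. = FALSE)
  }
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %s: %d match states, %s\n", x$label,
              x$match_count,
              if (is.na(x$mu)) "uncalibrated"
              else sprintf("Gumbel mu=%.2f lambda=%.3f", x$mu, x$lambda)))
  if (length(x$reference_map) > 0) {
    cat("  reference map:",
        paste(names(x$reference_map), x$reference_map, sep = ":",
              collapse = " "), "\n")
  }
  invisible(x)
}

is_calibrated <- function(hmm) !is.na(hmm$mu) && !is.na(hmm$lambda)

#' Consensus sequence of a profile
#'
#' @param hmm A `profile_hmm`.
#' @return Character string of per-match-state argmax residues.
#' @export
profile_consensus <- function(hmm) {
  paste(AA20[apply(hmm$match_em, 1, which.max)], collapse = "")
}

#' Build a profile HMM from a curated alignment
#'
#' Columns whose residue occupancy is at least `occupancy` become match
#' states; the rest are insert columns. Match emissions are observed counts
#' plus `pseudocount` times the background, normalised. Transitions are
#' estimated from the observed per-row state paths with additive smoothing
#' (`transition_pseudocount` per allowed target). Insert states emit the
#' background.
#'
#' @param msa An [aa_alignment()] (or tibble with `id`/`aligned`), >= 2 rows.
#' @param label Orthogroup name.
#' @param occupancy Match-column occupancy threshold (default 0.5).
#' @param pseudocount Emission pseudocount weight against the background
#'   (default 1.0).
#' @param transition_pseudocount Additive smoothing for transition counts
#'   (default 0.1).
#' @param reference Optional id of an alignment row anchoring residue labels.
#' @param reference_positions Optional named integer vector of positions in
#'   the ungapped reference sequence (e.g. `c(C101 = 101)`); positions whose
#'   column is a match state enter the profile's `reference_map`.
#' @param background Background frequencies (default [aa_background()]).
#' @param flank_loop Self-loop probability of the flanking insert states.
#' @return A `profile_hmm`.
#' @export
build_profile <- function(msa, label, occupancy = 0.5, pseudocount = 1.0,
                          transition_pseudocount = 0.1, reference = NULL,
                          reference_positions = NULL,
                          background = aa_background(), flank_loop = 0.9) {
  rows <- if ("aligned" %in% names(msa)) msa$aligned else msa$sequence
  ids <- msa$id
  if (length(rows) < 2) stop("profile needs an MSA with >= 2 rows", call. = FALSE)
  chars <- do.call(rbind, strsplit(toupper(rows), ""))
  nres <- chars != "-"
  occ <- colMeans(nres)
  match_cols <- which(occ >= occupancy)
  L <- length(match_cols)
  if (L == 0) stop("no column reaches the occupancy threshold", call. = FALSE)

  # emissions
  match_em <- t(vapply(match_cols, function(j) {
    obs <- chars[, j]
    counts <- table(factor(obs[obs %in% AA20], levels = AA20))
    p <- as.numeric(counts) + pseudocount * background
    p / sum(p)
  }, numeric(20)))

  # per-row state paths over core states; column -> match index
  col_to_k <- cumsum(seq_along(occ) %in% match_cols)
  is_match_col <- seq_along(occ) %in% match_cols
  counts <- matrix(0, nrow = L, ncol = 7, dimnames = list(NULL, TRANS_COLS))
  for (r in seq_len(nrow(chars))) {
    st <- character(0); kk <- integer(0)
    for (j in seq_along(occ)) {
      if (is_match_col[j]) {
        st <- c(st, if (nres[r, j]) "M" else "D"); kk <- c(kk, col_to_k[j])
      } else if (nres[r, j]) {
        k <- col_to_k[j]
        if (k >= 1 && k <= L - 1) { st <- c(st, "I"); kk <- c(kk, k) }
      }
    }
    keep <- which(st == "M")
    if (length(keep) == 0) next
    sel <- seq(min(keep), max(keep)) # drop leading/trailing deletes
    st <- st[sel]; kk <- kk[sel]
    if (length(st) < 2) next
    for (t in seq_len(length(st) - 1)) {
      key <- paste0(st[t], st[t + 1])
      if (key %in% TRANS_COLS) counts[kk[t], key] <- counts[kk[t], key] + 1
    }
  }

  trans <- matrix(0, nrow = L, ncol = 7, dimnames = list(NULL, TRANS_COLS))
  tp <- transition_pseudocount
  if (L > 1) {
    for (k in seq_len(L - 1)) {
      m_targets <- if (k <= L - 2) c("MM", "MI", "MD") else c("MM", "MI")
      cm <- counts[k, m_targets] + tp
      trans[k, m_targets] <- cm / sum(cm)
      ci <- counts[k, c("IM", "II")] + tp
      trans[k, c("IM", "II")] <- ci / sum(ci)
      if (k >= 2) {
        d_targets <- if (k <= L - 2) c("DM", "DD") else "DM"
        cd <- counts[k, d_targets] + tp
        trans[k, d_targets] <- cd / sum(cd)
      }
    }
  }

  reference_map <- integer()
  if (!is.null(reference) && !is.null(reference_positions)) {
    r <- match(reference, ids)
    if (is.na(r)) stop("reference id not in MSA", call. = FALSE)
    res_cols <- which(nres[r, ]) # column of each ungapped reference residue
    bad <- reference_positions > length(res_cols)
    mapped <- vapply(reference_positions[!bad], function(p) {
      j <- res_cols[p]
      if (is_match_col[j]) col_to_k[j] else NA_integer_
    }, integer(1))
    dropped <- c(names(reference_positions)[bad], names(mapped)[is.na(mapped)])
    if (length(dropped) > 0) {
      warning("reference positions not on match columns: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    reference_map <- mapped[!is.na(mapped)]
  }

  new_profile_hmm(label, match_em, trans, background,
                  reference_map = reference_map, flank_loop = flank_loop)
}

# assemble the log-space inputs of the C++ kernels for one sequence
hmm_dp_inputs <- function(hmm, chars) {
  idx <- residue_index(chars)
  n <- length(idx)
  L <- hmm$match_count
  log_bg <- log(hmm$background)
  log_ins <- log(hmm$insert_em)
  log_me <- log(hmm$match_em) # L x 20
  NL <- ifelse(idx < 20, log_bg[idx + 1], 0)
  IE <- ifelse(idx < 20, log_ins[idx + 1], 0)
  ME <- matrix(0, nrow = L, ncol = n)
  known <- idx < 20
  if (any(known)) ME[, known] <- log_me[, idx[known] + 1, drop = FALSE]
  TR <- log(hmm$trans)
  TR[!is.finite(TR)] <- -1e300
  list(ME = ME, IE = IE, NL = NL, TR = TR,
       ln_loop = log(hmm$flank_loop), ln_exit = log(1 - hmm$flank_loop))
}

seq_chars <- function(seq) {
  if (is.data.frame(seq)) seq <- seq$sequence[1]
  split_residues(seq)
}

#' Forward bit score of a sequence against a profile
#'
#' Log2 odds of the summed probability over all state paths versus the
#' background i.i.d. null model. Computed in log space (no underflow for
#' sequences up to at least 10,000 residues).
#'
#' @param hmm A `profile_hmm`.
#' @param seq Character string or single-row tibble with a `sequence` column.
#' @return Bit score (numeric scalar; `-Inf` if no path exists).
#' @export
forward_score <- function(hmm, seq) {
  chars <- seq_chars(seq)
  inp <- hmm_dp_inputs(hmm, chars)
  lp <- hmm_forward_cpp(inp$ME, inp$IE, inp$NL, inp$TR, inp$ln_loop, inp$ln_exit)
  if (lp < -1e290) return(-Inf)
  (lp - sum(inp$NL)) / log(2)
}

#' Viterbi alignment of a sequence to a profile
#'
#' Maximum-probability state path; its bit score is never above the forward
#' score. Each residue maps to exactly one match, insert, or flank state;
#' skipped match states appear as delete rows with `residue = NA`.
#'
#' @inheritParams forward_score
#' @return List with `score` (bits) and `path`, a tibble with columns
#'   `residue` (sequence position or `NA` for deletes), `state` (one of
#'   N/M/I/D/C) and `match_state` (match index or `NA`).
#' @export
viterbi_align <- function(hmm, seq) {
  chars <- seq_chars(seq)
  inp <- hmm_dp_inputs(hmm, chars)
  res <- hmm_viterbi_cpp(inp$ME, inp$IE, inp$NL, inp$TR, inp$ln_loop, inp$ln_exit)
  if (res$score < -1e290) {
    return(list(score = -Inf,
                path = tibble(residue = integer(), state = character(),
                              match_state = integer())))
  }
  score <- (res$score - sum(inp$NL)) / log(2)
  state_chr <- c("N", "M", "I", "C")[res$type + 1]
  path <- tibble(residue = seq_along(chars), state = state_chr,
                 match_state = ifelse(res$k > 0, res$k, NA_integer_))
  # interleave delete rows for skipped match states
  m_rows <- which(path$state == "M")
  out <- list()
  prev_k <- 0L
  last_end <- 0L
  for (i in m_rows) {
    k <- path$match_state[i]
    if (i > last_end + 1) { # N-flank / insert residues before this match
      out[[length(out) + 1]] <- path[(last_end + 1):(i - 1), ]
    }
    if (k > prev_k + 1) { # skipped match states were deleted
      out[[length(out) + 1]] <- tibble(residue = NA_integer_, state = "D",
                                       match_state = seq(prev_k + 1L, k - 1L))
    }
    out[[length(out) + 1]] <- path[i, ]
    prev_k <- k
    last_end <- i
  }
  if (last_end < nrow(path)) out[[length(out) + 1]] <- path[(last_end + 1):nrow(path), ]
  list(score = score, path = dplyr::bind_rows(out))
}

# maximum-likelihood Gumbel fit (distribution of maxima)
fit_gumbel <- function(x) {
  if (stats::sd(x) < 1e-8) stop("degenerate score variance", call. = FALSE)
  xbar <- mean(x)
  shift <- min(x)
  g <- function(beta) {
    w <- exp(-(x - shift) / beta)
    beta - xbar + sum(x * w) / sum(w)
  }
  beta0 <- stats::sd(x) * sqrt(6) / pi
  lo <- beta0 / 50; hi <- beta0 * 50
  while (g(lo) * g(hi) > 0 && hi < beta0 * 1e6) { lo <- lo / 10; hi <- hi * 10 }
  beta <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  mu <- shift - beta * log(mean(exp(-(x - shift) / beta)))
  c(mu = mu, lambda = 1 / beta)
}

#' Calibrate a profile's E-value statistics
#'
#' Scores `n_samples` random background sequences (length = number of match
#' states) with [forward_score()] and fits a Gumbel distribution by maximum
#' likelihood. E-values then follow
#' `E = dbsize * exp(-lambda * (score - mu))`.
#'
#' @param hmm A `profile_hmm`.
#' @param n_samples Number of background samples (>= 100; default 200).
#' @param seed Integer seed making the calibration reproducible.
#' @return The profile with `mu` and `lambda` filled in.
#' @export
calibrate_profile <- function(hmm, n_samples = 200, seed = 1) {
  if (n_samples < 100) stop("calibration needs n_samples >= 100", call. = FALSE)
  scores <- withr::with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      s <- paste(sample(AA20, hmm$match_count, replace = TRUE,
                        prob = hmm$background), collapse = "")
      forward_score(hmm, s)
    }, numeric(1))
  })
  fit <- fit_gumbel(scores)
  hmm$mu <- unname(fit["mu"])
  hmm$lambda <- unname(fit["lambda"])
  hmm
}

#' E-value of a bit score
#'
#' @param hmm A calibrated `profile_hmm`.
#' @param score Bit score(s).
#' @param dbsize Number of sequences searched.
#' @return Expected number of background hits at or above `score`.
#' @export
profile_evalue <- function(hmm, score, dbsize) {
  if (!is_calibrated(hmm)) stop("profile is not calibrated", call. = FALSE)
  dbsize * exp(-hmm$lambda * (score - hmm$mu))
}

#' Scan a proteome against a set of profiles
#'
#' Scores every record against every profile and assigns each record to the
#' best-matching profile among those reaching the E-value threshold (ties
#' broken by lexicographic profile label). Records with no qualifying hit
#' stay unassigned (`label = NA`).
#'
#' @param proteome Tibble of protein records (`id`, `sequence`, optional
#'   `taxon`); may be empty.
#' @param profiles Named list of calibrated `profile_hmm`s.
#' @param evalue_threshold Assignment threshold (default `1e-20`).
#' @param dbsize Database size for E-values (default: number of records).
#' @return Tibble with one row per record: `id`, `taxon`, `label`,
#'   `bitscore`, `evalue`. The full bit-score matrix is attached as the
#'   `"scores"` attribute.
#' @export
scan_proteome <- function(proteome, profiles, evalue_threshold = 1e-20,
                          dbsize = NULL) {
  labels <- unname(vapply(profiles, function(p) p$label, character(1)))
  if (is.null(names(profiles))) names(profiles) <- labels
  bad <- !vapply(profiles, is_calibrated, logical(1))
  if (any(bad)) {
    stop("uncalibrated profiles: ", paste(labels[bad], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(proteome)
  if (is.null(dbsize)) dbsize <- max(n, 1L)
  taxon <- if ("taxon" %in% names(proteome)) proteome$taxon else rep(NA_character_, n)
  if (n == 0) {
    out <- tibble(id = character(), taxon = character(), label = character(),
                  bitscore = numeric(), evalue = numeric())
    attr(out, "scores") <- matrix(numeric(), 0, length(profiles),
                                  dimnames = list(NULL, labels))
    return(out)
  }
  scores <- vapply(profiles, function(p) {
    vapply(proteome$sequence, function(s) forward_score(p, s), numeric(1),
           USE.NAMES = FALSE)
  }, numeric(n))
  scores <- matrix(scores, nrow = n, dimnames = list(proteome$id, labels))
  ev <- vapply(seq_along(profiles), function(j) {
    profile_evalue(profiles[[j]], scores[, j], dbsize)
  }, numeric(n))
  ev <- matrix(ev, nrow = n)
  pick <- function(i) {
    qual <- which(ev[i, ] <= evalue_threshold)
    if (length(qual) == 0) {
      j <- order(-scores[i, ], labels)[1]
      return(tibble(label = NA_character_, bitscore = scores[i, j],
                    evalue = ev[i, j]))
    }
    j <- qual[order(-scores[i, qual], labels[qual])[1]]
    tibble(label = labels[j], bitscore = scores[i, j], evalue = ev[i, j])
  }
  best <- dplyr::bind_rows(purrr::map(seq_len(n), pick))
  out <- dplyr::bind_cols(tibble(id = proteome$id, taxon = taxon), best)
  attr(out, "scores") <- scores
  out
}

#' Sample a sequence from a profile
#'
#' Walks the core state machine from the first to the last match state,
#' emitting match residues from the match distributions and insert residues
#' from the insert (background) distribution.
#'
#' @param hmm A `profile_hmm`.
#' @param seed Optional integer seed; the same seed reproduces the sample.
#' @return List with `sequence` (string) and `path` (tibble of `state`,
#'   `match_state` per emitted/skipped state).
#' @export
sample_sequence <- function(hmm, seed = NULL) {
  run <- function() {
    L <- hmm$match_count
    st <- character(0); kk <- integer(0); res <- character(0)
    emit_m <- function(k) sample(AA20, 1, prob = hmm$match_em[k, ])
    emit_i <- function() sample(AA20, 1, prob = hmm$insert_em)
    k <- 1L; state <- "M"
    repeat {
      if (state == "M") {
        st <- c(st, "M"); kk <- c(kk, k); res <- c(res, emit_m(k))
        if (k == L) break
        p <- hmm$trans[k, c("MM", "MI", "MD")]
      } else if (state == "I") {
        st <- c(st, "I"); kk <- c(kk, k); res <- c(res, emit_i())
        p <- c(hmm$trans[k, "IM"], hmm$trans[k, "II"], 0)
      } else { # D
        st <- c(st, "D"); kk <- c(kk, k); res <- c(res, NA_character_)
        p <- c(hmm$trans[k, "DM"], 0, hmm$trans[k, "DD"])
      }
      nxt <- sample(c("M", "I", "D"), 1, prob = p)
      if (state == "M" && nxt == "I") { state <- "I" }
      else if (state == "I" && nxt == "I") { state <- "I" }
      else if (nxt == "M") { state <- "M"; k <- k + 1L }
      else { state <- "D"; k <- k + 1L }
    }
    list(sequence = paste(res[!is.na(res)], collapse = ""),
         path = tibble(state = st, match_state = ifelse(st == "I", NA_integer_, kk)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

fmt6 <- function(x) trimws(formatC(x, digits = 6, format = "g"))

#' Serialize a profile to plain text
#'
#' Writes the documented plain-text profile format (label, match count,
#' calibration, background, reference map, then one line per match state with
#' 20 emission and 7 transition values at 6 significant digits). A profile
#' read back with [read_profile()] and rewritten is byte-identical.
#'
#' @param hmm A `profile_hmm`.
#' @param path Output path.
#' @export
write_profile <- function(hmm, path) {
  rm <- hmm$reference_map
  lines <- c(
    "dnaserep-profile 1",
    paste("label", hmm$label),
    paste("match_count", hmm$match_count),
    paste("flank_loop", fmt6(hmm$flank_loop)),
    paste("calibration", fmt6(hmm$mu), fmt6(hmm$lambda)),
    paste("background", paste(fmt6(hmm$background), collapse = " ")),
    paste("refmap", if (length(rm) == 0) "-" else
      paste(names(rm), rm, sep = ":", collapse = " ")),
    vapply(seq_len(hmm$match_count), function(k) {
      paste("state", k, paste(fmt6(hmm$match_em[k, ]), collapse = " "),
            paste(fmt6(hmm$trans[k, ]), collapse = " "))
    }, character(1)),
    "end")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text profile
#'
#' @param path Path written by [write_profile()].
#' @return A `profile_hmm` (values at the serialized 6-digit precision).
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "dnaserep-profile 1") stop("not a profile file", call. = FALSE)
  field <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))][1]
    sub(paste0("^", key, " "), "", ln)
  }
  label <- field("label")
  L <- as.integer(field("match_count"))
  flank_loop <- as.numeric(field("flank_loop"))
  cal <- as.numeric(strsplit(field("calibration"), " ")[[1]])
  background <- as.numeric(strsplit(field("background"), " ")[[1]])
  names(background) <- AA20
  rm_str <- field("refmap")
  reference_map <- integer()
  if (rm_str != "-") {
    parts <- strsplit(strsplit(rm_str, " ")[[1]], ":")
    reference_map <- setNames(as.integer(vapply(parts, `[`, "", 2)),
                              vapply(parts, `[`, "", 1))
  }
  state_lines <- lines[startsWith(lines, "state ")]
  if (length(state_lines) != L) stop("corrupt profile file", call. = FALSE)
  vals <- lapply(state_lines, function(ln) as.numeric(strsplit(ln, " ")[[1]][-(1:2)]))
  match_em <- do.call(rbind, lapply(vals, function(v) v[1:20]))
  trans <- do.call(rbind, lapply(vals, function(v) v[21:27]))
  new_profile_hmm(label, match_em, trans, background,
                  reference_map = reference_map,
                  mu = cal[1], lambda = cal[2], flank_loop = flank_loop,
                  tol = 1e-3)
}

#' Export hits as TSV
#'
#' @param calls Tibble from [scan_proteome()] or [classify_sequences()].
#' @param path Output path.
#' @export
write_hits <- function(calls, path) {
  readr::write_tsv(calls[, c("id", "label", "bitscore", "evalue")], path)
  invisible(path)
}
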