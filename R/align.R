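#' Protein alignments
#'
#' An `aa_alignment` is a tibble with columns `id` and `aligned` (equal-length
#' gapped sequences) carrying `score` and `columns` attributes. Removing the
#' gaps from each row reproduces the input sequences.
#'
#' @param rows Tibble with `id` and `aligned` columns.
#' @param score Alignment score in substitution-matrix units (or `NA`).
#' @return An `aa_alignment` object.
#' @export
aa_alignment <- function(rows, score = NA_real_) {
  stopifnot(is.data.frame(rows), all(c("id", "aligned") %in% names(rows)))
  widths <- nchar(rows$aligned)
  if (length(unique(widths)) != 1) {
    stop("gapped sequences must have equal length", call. = FALSE)
  }
  out <- as_tibble(rows[, c("id", "aligned")])
  attr(out, "score") <- score
  attr(out, "columns") <- widths[1]
  class(out) <- c("aa_alignment", class(out))
  out
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %d rows x %d columns, score %s\n",
              nrow(x), attr(x, "columns"),
              format(attr(x, "score"), digits = 6)))
  NextMethod()
}

#' Remove gaps from alignment rows
#'
#' @param aln An [aa_alignment()].
#' @return Tibble with `id` and ungapped `sequence` columns.
#' @export
degap <- function(aln) {
  tibble(id = aln$id, sequence = gsub("-", "", aln$aligned, fixed = TRUE))
}

as_sequence_pair <- function(a, b) {
  pick <- function(x, default_id) {
    if (is.data.frame(x)) {
      check_records(x, 1L)
      list(id = x$id[1], sequence = x$sequence[1])
    } else {
      list(id = default_id, sequence = as.character(x))
    }
  }
  list(a = pick(a, "a"), b = pick(b, "b"))
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch / Gotoh global alignment. A gap run of length k costs
#' `gap_open + k * gap_extend`. Traceback ties prefer the diagonal, then the
#' vertical, then the horizontal move, which makes the alignment
#' deterministic. X scores 0 against every residue.
#'
#' @param a,b Sequences: character strings or single-row tibbles with `id`
#'   and `sequence`.
#' @param gap_open Gap-opening penalty (default 11).
#' @param gap_extend Gap-extension penalty per residue (default 1).
#' @param submat Substitution matrix (default [substitution_matrix()]).
#' @return An [aa_alignment()] with two rows.
#' @export
global_align <- function(a, b, gap_open = 11, gap_extend = 1,
                         submat = substitution_matrix()) {
  pair <- as_sequence_pair(a, b)
  ca <- split_residues(pair$a$sequence)
  cb <- split_residues(pair$b$sequence)
  S <- submat[ca, cb, drop = FALSE]
  res <- affine_align_cpp(S, gap_open, gap_extend)
  ga <- ifelse(res$ai > 0, ca[pmax(res$ai, 1)], "-")
  gb <- ifelse(res$bi > 0, cb[pmax(res$bi, 1)], "-")
  aa_alignment(
    tibble(id = c(pair$a$id, pair$b$id),
           aligned = c(paste(ga, collapse = ""), paste(gb, collapse = ""))),
    score = res$score)
}

#' Percent identity of a pairwise alignment
#'
#' 100 x (identical residue pairs) / (columns where both rows hold residues).
#' Columns containing a gap in either row do not enter the denominator, so
#' terminal overhangs do not dilute the identity.
#'
#' @param aln A two-row [aa_alignment()].
#' @return Percentage in `[0, 100]` (unrounded; round for reporting).
#' @export
percent_identity <- function(aln) {
  if (nrow(aln) != 2) stop("percent_identity needs exactly 2 rows", call. = FALSE)
  a <- strsplit(aln$aligned[1], "")[[1]]
  b <- strsplit(aln$aligned[2], "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) return(0)
  100 * sum(a[both] == b[both]) / sum(both)
}

#' All-pairs identity matrix with clustered ordering
#'
#' Aligns every pair of records with [global_align()], computes percent
#' identities, and orders rows/columns by average-linkage hierarchical
#' clustering of the distance `100 - identity`.
#'
#' @param records Tibble of protein records (`id`, `sequence`); at least 2.
#' @param ... Passed to [global_align()].
#' @return An `identity_matrix` object: list with `identity` and `distance`
#'   matrices, `labels`, clustered `order`, and the `hclust` tree.
#' @export
identity_matrix <- function(records, ...) {
  check_records(records, 2L)
  n <- nrow(records)
  ids <- records$id
  pid <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      aln <- global_align(records[i, ], records[j, ], ...)
      pid[i, j] <- pid[j, i] <- percent_identity(aln)
    }
  }
  d <- 100 - pid
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(identity = pid, distance = d, labels = ids,
                 order = ids[hc$order], hclust = hc),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("<identity_matrix> %d sequences; clustered order: %s\n",
              length(x$labels), paste(x$order, collapse = ", ")))
  print(round(x$identity, 1))
  invisible(x)
}

#' Export an identity matrix as TSV
#'
#' Tab-separated with a header row and a leading label column; identities
#' rounded to the nearest integer for reporting.
#'
#' @param x An `identity_matrix`.
#' @param path Output path.
#' @export
write_identity_matrix <- function(x, path) {
  m <- round(x$identity)
  df <- as_tibble(m, rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}

# internal gapped-profile representation for progressive alignment
msa_profile <- function(ids, rows) {
  L <- nchar(rows[1])
  chars <- do.call(rbind, strsplit(rows, ""))
  letters21 <- c(AA20, "X")
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(chars[, j], levels = letters21))
    as.numeric(tab) / length(rows)
  }, numeric(21))
  list(ids = ids, rows = rows, freq = matrix(freq, nrow = 21))
}

merge_profiles <- function(pa, pb, gap_open, gap_extend, submat) {
  letters21 <- c(AA20, "X")
  S <- t(pa$freq) %*% submat[letters21, letters21] %*% pb$freq
  res <- affine_align_cpp(S, gap_open, gap_extend)
  expand <- function(rows, idx) {
    mat <- do.call(rbind, strsplit(rows, ""))
    vapply(seq_along(rows), function(r) {
      paste(ifelse(idx > 0, mat[r, pmax(idx, 1)], "-"), collapse = "")
    }, character(1))
  }
  msa_profile(c(pa$ids, pb$ids),
              c(expand(pa$rows, res$ai), expand(pb$rows, res$bi)))
}

#' Progressive multiple sequence alignment
#'
#' Builds a UPGMA guide tree from all-pairs identity distances, then merges
#' sub-alignments by profile-profile global alignment (column scores are
#' frequency-weighted substitution scores; gap columns carry zero weight).
#' Row order in the result equals the input order.
#'
#' @param records Tibble of protein records; a single record is returned
#'   unchanged as a one-row alignment.
#' @param gap_open,gap_extend Affine gap penalties (defaults 11 / 1).
#' @param submat Substitution matrix.
#' @return An [aa_alignment()] with `nrow(records)` rows.
#' @export
progressive_msa <- function(records, gap_open = 11, gap_extend = 1,
                            submat = substitution_matrix()) {
  check_records(records, 1L)
  n <- nrow(records)
  if (n == 1) {
    return(aa_alignment(tibble(id = records$id, aligned = records$sequence)))
  }
  profiles <- purrr::map(seq_len(n), function(i) {
    msa_profile(records$id[i], toupper(records$sequence[i]))
  })
  if (n == 2) {
    merged <- merge_profiles(profiles[[1]], profiles[[2]],
                             gap_open, gap_extend, submat)
  } else {
    im <- identity_matrix(records, gap_open = gap_open,
                          gap_extend = gap_extend, submat = submat)
    hc <- im$hclust
    nodes <- vector("list", n - 1)
    fetch <- function(k) if (k < 0) profiles[[-k]] else nodes[[k]]
    for (s in seq_len(n - 1)) {
      nodes[[s]] <- merge_profiles(fetch(hc$merge[s, 1]), fetch(hc$merge[s, 2]),
                                   gap_open, gap_extend, submat)
    }
    merged <- nodes[[n - 1]]
  }
  ord <- match(records$id, merged$ids)
  aa_alignment(tibble(id = merged$ids[ord], aligned = merged$rows[ord]))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (via \pkg{ape}); recovers any additive tree
#' exactly. Used as the orthogroup monophyly sanity check.
#'
#' @param d An `identity_matrix`, `dist`, or symmetric numeric matrix with
#'   labels; at least 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "identity_matrix")) d <- d$distance
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (is.null(rownames(d))) stop("distance matrix needs labels", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (nrow(d) < 3) stop("neighbor-joining needs at least 3 labels", call. = FALSE)
  ape::nj(stats::as.dist(d))
}
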