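#' @useDynLib dnaserep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# the 20 standard amino acids, alphabetical one-letter order
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Robinson & Robinson amino-acid background frequencies, renormalised
ROBINSON_BG_RAW <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Amino-acid background frequencies
#'
#' Robinson-Robinson residue frequencies over the 20 standard amino acids,
#' renormalised to sum to one, in alphabetical one-letter order. Used as the
#' null model and as the pseudocount prior for profile emissions.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function() {
  bg <- ROBINSON_BG_RAW[AA20]
  bg / sum(bg)
}

# Kyte-Doolittle hydropathy scale
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

.dnaserep_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution scores with neutral X
#'
#' The standard BLOSUM62 matrix restricted to the 20 amino acids plus X,
#' with every score involving X set to 0 so that unknown residues neither
#' reward nor penalise an alignment.
#'
#' @return A 21 x 21 integer matrix with dimnames over `c(AA, "X")`.
#' @export
substitution_matrix <- function() {
  if (is.null(.dnaserep_cache$submat)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    letters21 <- c(AA20, "X")
    m <- env$BLOSUM62[letters21, letters21]
    m["X", ] <- 0L
    m[, "X"] <- 0L
    .dnaserep_cache$submat <- m
  }
  .dnaserep_cache$submat
}

# split a sequence string into residues, validating the alphabet
split_residues <- function(sequence, allow_gap = FALSE) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  ok <- c(AA20, "X", if (allow_gap) "-")
  bad <- setdiff(unique(chars), ok)
  if (length(bad) > 0) {
    stop("non-amino-acid characters in sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  chars
}

# residues -> 0-based indices into AA20; X -> 20L
residue_index <- function(chars) {
  idx <- match(chars, AA20) - 1L
  idx[chars == "X"] <- 20L
  idx
}

# net charge under the K/R = +1, D/E = -1, H = 0 convention
net_charge <- function(chars) {
  sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E"))
}

mean_hydropathy <- function(chars) {
  v <- KYTE_DOOLITTLE[chars]
  mean(v, na.rm = TRUE) # X has no defined hydropathy
}

check_records <- function(records, min_rows = 1L) {
  stopifnot(is.data.frame(records))
  if (!all(c("id", "sequence") %in% names(records))) {
    stop("records must have 'id' and 'sequence' columns", call. = FALSE)
  }
  if (nrow(records) < min_rows) {
    stop("need at least ", min_rows, " records", call. = FALSE)
  }
  if (anyDuplicated(records$id)) {
    stop("duplicate record ids", call. = FALSE)
  }
  if (any(!nzchar(records$sequence)) || any(!nzchar(records$id))) {
    stop("empty id or sequence", call. = FALSE)
  }
  invisible(records)
}
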