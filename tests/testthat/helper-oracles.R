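# Independent brute-force oracles used to verify the dynamic-programming
# implementations on small instances. These deliberately share no code with
# the package internals.

# exhaustive global affine alignment score: recursion over all alignments,
# gap runs cost open + len * ext, vertical and horizontal runs are distinct
oracle_align_score <- function(a, b, submat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  rec2 <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, submat[ca[i], cb[j]] + rec2(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- gap_extend + if (prev == "U") 0 else gap_open
      best <- max(best, -cost + rec2(i + 1, j, "U"))
    }
    if (j <= m) {
      cost <- gap_extend + if (prev == "L") 0 else gap_open
      best <- max(best, -cost + rec2(i, j + 1, "L"))
    }
    best
  }
  rec2(1, 1, "start")
}

# exhaustive forward/Viterbi: enumerate every state path of the glocal
# profile architecture (N flank -> M1 ... ML -> C flank) and sum (or max)
# path odds against the background null
oracle_hmm_score <- function(hmm, seq, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  comb <- if (mode == "sum") sum else max
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  L <- hmm$match_count
  bg <- hmm$background[chars]
  ins <- hmm$insert_em[chars]
  pn <- hmm$flank_loop
  me <- hmm$match_em
  tr <- hmm$trans
  cflank <- function(i) {
    if (i == n) return(1 - pn)
    (1 - pn) * prod(pn * bg[(i + 1):n])
  }
  rec <- function(state, k, i) {
    if (state == "M") {
      if (i >= n) return(0)
      p <- me[k, chars[i + 1]]
      i <- i + 1
      if (k == L) return(p * cflank(i))
      opts <- c(tr[k, "MM"] * rec("M", k + 1, i),
                tr[k, "MI"] * rec("I", k, i),
                if (tr[k, "MD"] > 0) tr[k, "MD"] * rec("D", k + 1, i) else NULL)
      p * comb(opts)
    } else if (state == "I") {
      if (i >= n) return(0)
      p <- ins[i + 1]
      i <- i + 1
      p * comb(c(tr[k, "IM"] * rec("M", k + 1, i),
                 tr[k, "II"] * rec("I", k, i)))
    } else { # D
      comb(c(tr[k, "DM"] * rec("M", k + 1, i),
             if (tr[k, "DD"] > 0) tr[k, "DD"] * rec("D", k + 1, i) else NULL))
    }
  }
  entries <- vapply(0:(n - 1), function(j) {
    pref <- if (j == 0) 1 else prod(pn * bg[seq_len(j)])
    pref * (1 - pn) * rec("M", 1, j)
  }, numeric(1))
  total <- comb(entries)
  log2(total / prod(bg))
}

# exhaustive Dollo minimum-loss count: enumerate ancestral labelings with a
# single gain (root state 1 counts as the gain on the root stem)
oracle_dollo_losses <- function(tree, present_tips) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  leaf_state <- as.integer(tree$tip.label %in% present_tips)
  best <- Inf
  for (mask in 0:(2^nnode - 1)) {
    internal <- as.integer(intToBits(mask))[seq_len(nnode)]
    state <- c(leaf_state, internal)
    gains <- state[ntip + 1] # root gain
    losses <- 0
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- state[tree$edge[e, 1]]; v <- state[tree$edge[e, 2]]
      if (p == 0 && v == 1) gains <- gains + 1
      if (p == 1 && v == 0) losses <- losses + 1
    }
    if (gains == 1) best <- min(best, losses)
  }
  best
}

# forward-simulate a presence pattern from an inferred event set
presence_from_events <- function(events, tree) {
  tips <- tree$tip.label
  under <- function(lbl) {
    v <- dnaserep:::node_by_label(tree, lbl)
    if (v <= length(tips)) tips[v]
    else tips[dnaserep:::descendant_tips(tree)[[v]]]
  }
  groups <- unique(events$orthogroup)
  cols <- lapply(groups, function(g) {
    ev <- events[events$orthogroup == g, ]
    gain <- ev[ev$event == "gain", ]
    present <- under(gain$child)
    for (i in which(ev$event == "loss")) {
      present <- setdiff(present, under(ev$child[i]))
    }
    tips %in% present
  })
  names(cols) <- groups
  dnaserep::presence_matrix(
    dplyr::bind_cols(tibble::tibble(taxon = tips),
                     tibble::as_tibble(cols, .name_repair = "minimal")))
}
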