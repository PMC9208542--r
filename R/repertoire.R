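#' Presence/absence matrices
#'
#' A `presence_matrix` is a wide tibble: one `taxon` column plus one logical
#' column per orthogroup.
#'
#' @param df Tibble with a `taxon` column and logical orthogroup columns.
#' @return A `presence_matrix`.
#' @export
presence_matrix <- function(df) {
  stopifnot(is.data.frame(df), "taxon" %in% names(df))
  ortho <- setdiff(names(df), "taxon")
  stopifnot(all(vapply(df[ortho], is.logical, logical(1))))
  if (anyDuplicated(df$taxon)) stop("duplicate taxa", call. = FALSE)
  structure(as_tibble(df), class = c("presence_matrix", class(as_tibble(df))))
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d taxa x %d orthogroups\n",
              nrow(x), ncol(x) - 1))
  NextMethod()
}

as_logical_matrix <- function(pm) {
  m <- as.matrix(pm[, setdiff(names(pm), "taxon")])
  rownames(m) <- pm$taxon
  m
}

#' Build a presence/absence matrix from orthogroup calls
#'
#' A cell is TRUE iff the taxon has at least one call assigned to that
#' orthogroup. Taxa with no calls appear as all-FALSE rows; taxa present in
#' the calls but missing from `taxa` are an error.
#'
#' @param calls Tibble with `taxon` and `label` columns (NA labels ignored).
#' @param taxa Character vector of taxa defining the row set and order.
#' @param orthogroups Column set and order (default [dnase_orthogroups()]).
#' @return A [presence_matrix()].
#' @export
build_matrix <- function(calls, taxa, orthogroups = dnase_orthogroups()) {
  assigned <- dplyr::filter(calls, !is.na(.data$label))
  unknown <- setdiff(unique(assigned$taxon), taxa)
  if (length(unknown) > 0) {
    stop("taxa in calls absent from taxa list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- matrix(FALSE, nrow = length(taxa), ncol = length(orthogroups),
              dimnames = list(taxa, orthogroups))
  hit <- assigned[assigned$label %in% orthogroups, c("taxon", "label")]
  if (nrow(hit) > 0) m[cbind(hit$taxon, hit$label)] <- TRUE
  presence_matrix(dplyr::bind_cols(tibble(taxon = taxa), as_tibble(m)))
}

#' Export / import a presence matrix as TSV
#'
#' Tab-separated, taxa as rows, orthogroups as columns, cells "1"/"0".
#'
#' @param pm A [presence_matrix()].
#' @param path File path.
#' @export
write_presence <- function(pm, path) {
  out <- dplyr::mutate(pm, dplyr::across(-"taxon", as.integer))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_presence
#' @export
read_presence <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  presence_matrix(dplyr::mutate(df, dplyr::across(-"taxon", \(x) x > 0)))
}

tree_edges <- function(tree) {
  ages <- attr(tree, "ages")
  tibble(parent = tree$edge[, 1], child = tree$edge[, 2],
         parent_label = node_label(tree, tree$edge[, 1]),
         child_label = node_label(tree, tree$edge[, 2]),
         older = ages[tree$edge[, 1]], younger = ages[tree$edge[, 2]])
}

# set of leaves under each node (node numbers -> tip index list)
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  }
  out <- vector("list", nnode)
  rec <- function(v) {
    if (v <= ntip) { out[[v]] <<- v; return(v) }
    tips <- unlist(lapply(kids[[v]], rec))
    out[[v]] <<- tips
    tips
  }
  rec(ntip + 1)
  out
}

#' Dollo parsimony gain/loss reconstruction
#'
#' For each orthogroup, places a single gain on the stem branch above the
#' most recent common ancestor of all presence leaves, and one loss on the
#' stem of every maximal subtree below the gain containing no presence leaf.
#' This is the minimum-loss reconstruction under the single-gain (Dollo)
#' model. Each event carries the time interval of its branch (parent age,
#' child age). A gain at the tree root has no parent age; its older bound is
#' `NA`.
#'
#' @param pm A [presence_matrix()]; every taxon must be a tree leaf.
#' @param tree A dated tree from [read_species_tree()] (with an `ages`
#'   attribute; computed with root age = max depth when absent).
#' @return Tibble of events: `orthogroup`, `event` ("gain"/"loss"),
#'   `parent`, `child` (node labels), `older`, `younger` (Myr), of class
#'   `dollo_events`.
#' @export
dollo_events <- function(pm, tree) {
  if (is.null(attr(tree, "ages"))) tree <- with_node_ages(tree)
  ages <- attr(tree, "ages")
  ntip <- length(tree$tip.label)
  missing_taxa <- setdiff(pm$taxon, tree$tip.label)
  if (length(missing_taxa) > 0) {
    stop("taxa not in tree: ", paste(missing_taxa, collapse = ", "),
         call. = FALSE)
  }
  desc <- descendant_tips(tree)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  mat <- as_logical_matrix(pm)
  orthogroups <- colnames(mat)

  one_group <- function(g) {
    present_taxa <- rownames(mat)[mat[, g]]
    if (length(present_taxa) == 0) {
      warning("orthogroup absent everywhere: ", g, call. = FALSE)
      return(NULL)
    }
    tips <- match(present_taxa, tree$tip.label)
    mrca <- if (length(tips) == 1) tips else ape::getMRCA(tree, tips)
    gain <- tibble(
      orthogroup = g, event = "gain",
      parent = if (mrca == root) NA_character_
               else node_label(tree, parent_of[mrca]),
      child = node_label(tree, mrca),
      older = if (mrca == root) NA_real_ else ages[parent_of[mrca]],
      younger = ages[mrca])
    # maximal absent subtrees strictly below the gain
    has_presence <- vapply(seq_along(desc), function(v) {
      any(desc[[v]] %in% tips)
    }, logical(1))
    in_gain <- desc[[mrca]]
    losses <- list()
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      under <- all(if (v <= ntip) v %in% in_gain else desc[[v]] %in% in_gain)
      if (!under || v == mrca) next
      if (!has_presence[v] && has_presence[p]) {
        losses[[length(losses) + 1]] <- tibble(
          orthogroup = g, event = "loss",
          parent = node_label(tree, p), child = node_label(tree, v),
          older = ages[p], younger = ages[v])
      }
    }
    dplyr::bind_rows(c(list(gain), losses))
  }
  out <- dplyr::bind_rows(purrr::map(orthogroups, one_group))
  class(out) <- c("dollo_events", class(out))
  attr(out, "tree") <- tree
  out
}

#' Date a tandem duplication from gain intervals
#'
#' The duplication interval is the child orthogroup's gain-branch interval,
#' intersected with the parent's presence span when the parent's own gain
#' does not predate it (a daughter gene cannot be older than its source).
#'
#' @param events A `dollo_events` tibble.
#' @param parent_orthogroup,child_orthogroup Orthogroup labels.
#' @return One-row tibble: `parent`, `child`, `older`, `younger`,
#'   `midpoint` (Myr).
#' @export
duplication_interval <- function(events, parent_orthogroup, child_orthogroup) {
  gain <- function(g) {
    row <- dplyr::filter(events, .data$orthogroup == g, .data$event == "gain")
    if (nrow(row) == 0) stop("no gain event for orthogroup ", g, call. = FALSE)
    row
  }
  g_child <- gain(child_orthogroup)
  g_parent <- gain(parent_orthogroup)
  older <- g_child$older
  if (!is.na(g_parent$older) && !is.na(older) && g_parent$older < older) {
    older <- g_parent$older
  }
  younger <- g_child$younger
  tibble(parent = parent_orthogroup, child = child_orthogroup,
         older = older, younger = younger, midpoint = (older + younger) / 2)
}

#' Export events as TSV
#'
#' Columns: orthogroup, event, parent, child, older_myr, younger_myr.
#'
#' @param events A `dollo_events` tibble.
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  out <- tibble(orthogroup = events$orthogroup, event = events$event,
                parent = events$parent, child = events$child,
                older_myr = events$older, younger_myr = events$younger)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read / write gene coordinate tables
#'
#' BED-like 6-column TSV: chrom, start, end, gene, score, strand, with
#' 0-based half-open coordinates. No header.
#'
#' @param path File path.
#' @export
read_gene_table <- function(path) {
  readr::read_tsv(path, col_names = c("chromosome", "start", "end", "gene",
                                      "score", "strand"),
                  col_types = "ciicic")
}

#' @rdname read_gene_table
#' @param loci Tibble with `gene`, `chromosome`, `start`, `end`, `strand`.
#' @export
write_gene_table <- function(loci, path) {
  out <- tibble(chromosome = loci$chromosome, start = loci$start,
                end = loci$end, gene = loci$gene,
                score = loci$score %||% 0L, strand = loci$strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Detect the local arrangement of a gene pair
#'
#' Coordinates are 0-based half-open; strand "+" transcribes left to right.
#' Head-to-head means divergent strands with the minus-strand gene upstream
#' (5' ends facing each other, as in a bidirectional promoter); tail-to-tail
#' means convergent strands; same-strand neighbours are tandem. Genes on
#' different chromosomes are UNLINKED with distance -1. Overlapping spans get
#' distance 0 with a warning.
#'
#' @param loci Gene table (tibble with `gene`, `chromosome`, `start`, `end`,
#'   `strand`) containing both genes.
#' @param gene_a,gene_b Gene names.
#' @param all_genes Optional table used to count intervening genes
#'   (default: `loci`).
#' @return One-row tibble: `gene_a`, `gene_b`, `arrangement`, `distance`,
#'   `intervening`.
#' @export
detect_synteny <- function(loci, gene_a, gene_b, all_genes = loci) {
  row_of <- function(g) {
    r <- loci[loci$gene == g, ]
    if (nrow(r) == 0) stop("gene not in table: ", g, call. = FALSE)
    r[1, ]
  }
  a <- row_of(gene_a); b <- row_of(gene_b)
  if (a$chromosome != b$chromosome) {
    return(tibble(gene_a = gene_a, gene_b = gene_b, arrangement = "UNLINKED",
                  distance = -1, intervening = NA_integer_))
  }
  left <- if (a$start <= b$start) a else b
  right <- if (a$start <= b$start) b else a
  gap_lo <- left$end; gap_hi <- right$start
  distance <- max(0, gap_hi - gap_lo)
  if (gap_hi < gap_lo) warning("overlapping gene spans", call. = FALSE)
  arrangement <-
    if (left$strand == right$strand) "TANDEM_SAME_STRAND"
    else if (left$strand == "-") "HEAD_TO_HEAD"
    else "TAIL_TO_TAIL"
  inter <- dplyr::filter(all_genes,
                         .data$chromosome == a$chromosome,
                         !(.data$gene %in% c(gene_a, gene_b)),
                         .data$start >= gap_lo, .data$end <= gap_hi)
  tibble(gene_a = gene_a, gene_b = gene_b, arrangement = arrangement,
         distance = distance, intervening = nrow(inter))
}
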