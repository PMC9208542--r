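#' Read protein sequences from FASTA
#'
#' Reads a (possibly aligned) protein FASTA file into a tibble. The taxon is
#' recovered from a `taxon=...` token in the description when present, as
#' written by [write_fasta()].
#'
#' @param path Path to a FASTA file.
#' @param aligned If `TRUE`, gap characters (`-`) are kept and returned in an
#'   `aligned` column; otherwise gaps are an error.
#' @return A tibble with columns `id`, `taxon`, `description` and `sequence`
#'   (or `aligned` when `aligned = TRUE`).
#' @export
read_fasta <- function(path, aligned = FALSE) {
  set <- Biostrings::readAAStringSet(path)
  header <- names(set)
  id <- sub("\\s.*$", "", header)
  description <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  taxon <- ifelse(grepl("taxon=(\\S+)", description),
                  sub(".*taxon=(\\S+).*", "\\1", description), NA_character_)
  seqs <- toupper(as.character(set))
  out <- tibble(id = id, taxon = taxon, description = description)
  if (aligned) {
    out$aligned <- unname(seqs)
  } else {
    out$sequence <- unname(gsub("\\*$", "", seqs))
    purrr::walk(out$sequence, split_residues)
  }
  check_records(if (aligned) dplyr::rename(out, sequence = "aligned") else out,
                min_rows = 0L)
  out
}

#' Write protein sequences to FASTA
#'
#' @param records Tibble with `id` and `sequence` (or `aligned`) columns;
#'   optional `taxon` and `description` columns are folded into the header.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  seq_col <- if ("aligned" %in% names(records)) "aligned" else "sequence"
  lines <- purrr::pmap(records, function(...) {
    row <- list(...)
    desc <- row$description %||% ""
    if (!is.null(row$taxon) && !is.na(row$taxon) &&
        !grepl("taxon=", desc)) {
      desc <- trimws(paste(desc, paste0("taxon=", row$taxon)))
    }
    header <- paste0(">", row$id, if (nzchar(desc)) paste0(" ", desc))
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", row[[seq_col]])
    paste0(header, "\n", sub("\n$", "", body))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a dated species tree from Newick
#'
#' Branch lengths are interpreted as absolute time (Myr). Node ages are
#' computed from depths, with the root age defaulting to the maximum
#' root-to-tip path length (appropriate for an ultrametric chronogram).
#'
#' @param path Path to a Newick file, or a Newick string.
#' @param root_age Optional root age in Myr overriding the default.
#' @return An `ape::phylo` tree with an `ages` attribute: a numeric vector of
#'   node ages indexed by node number (tips first, then internal nodes).
#' @export
read_species_tree <- function(path, root_age = NULL) {
  tree <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  with_node_ages(tree, root_age)
}

# attach an ages attribute (Myr before present) to a phylo object
with_node_ages <- function(tree, root_age = NULL) {
  stopifnot(inherits(tree, "phylo"))
  depth <- ape::node.depth.edgelength(tree)
  if (is.null(root_age)) root_age <- max(depth[seq_len(length(tree$tip.label))])
  ages <- root_age - depth
  if (is.null(tree$node.label) || !any(nzchar(tree$node.label))) {
    tree$node.label <- paste0("node", seq_len(tree$Nnode))
  }
  attr(tree, "ages") <- ages
  tree
}

node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  ifelse(node <= ntip, tree$tip.label[node], tree$node.label[node - ntip])
}

node_by_label <- function(tree, label) {
  ntip <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (is.na(j)) stop("label not in tree: ", label, call. = FALSE)
  j + ntip
}
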