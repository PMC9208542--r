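#' Pipeline orchestration
#'
#' Thin, file-to-file wrappers over the package functions, mirroring the
#' stages of the repertoire analysis: build profiles from curated
#' alignments, classify a proteome, reconstruct dated gain/loss events, and
#' emit a synthetic fixture bundle. All outputs are deterministic given
#' identical inputs, config and seed; tables are sorted by (taxon, id).
#' The `exec/dnaserep` script exposes these as shell subcommands.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' @return Named list of the pipeline defaults: E-value threshold, match
#'   occupancy, calibration samples, flank self-loop, and the feature
#'   constants of [feature_params()].
#' @export
default_run_config <- function() {
  c(list(evalue_threshold = 1e-20, occupancy = 0.5, pseudocount = 1.0,
         transition_pseudocount = 0.1, calibration_samples = 200,
         flank_loop = 0.9, seed = 1),
    feature_params())
}

#' Build and calibrate profiles from a directory of alignments
#'
#' Every `*.fa` / `*.fasta` aligned-FASTA file in `alignments_dir` becomes
#' one calibrated profile named after the file stem. A malformed alignment
#' is reported as a named failure; the remaining profiles are still built.
#'
#' @param alignments_dir Directory of aligned-FASTA files.
#' @param out_dir Output directory for `<label>.hmm` profile files.
#' @param seed Calibration seed.
#' @param ... Passed to [build_profile()].
#' @return Invisible tibble with `label`, `path`, `ok`, `error`.
#' @export
cmd_build_profiles <- function(alignments_dir, out_dir, seed = 1, ...) {
  files <- sort(list.files(alignments_dir, pattern = "\\.(fa|fasta)$",
                           full.names = TRUE))
  if (length(files) == 0) {
    stop("no alignment files in ", alignments_dir, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- purrr::imap(files, function(f, i) {
    label <- sub("\\.(fa|fasta)$", "", basename(f))
    out <- file.path(out_dir, paste0(label, ".hmm"))
    tryCatch({
      msa <- read_fasta(f, aligned = TRUE)
      hmm <- build_profile(msa, label, ...)
      hmm <- calibrate_profile(hmm, seed = seed + i)
      write_profile(hmm, out)
      tibble(label = label, path = out, ok = TRUE, error = NA_character_)
    }, error = function(e) {
      tibble(label = label, path = out, ok = FALSE,
             error = conditionMessage(e))
    })
  })
  invisible(dplyr::bind_rows(res))
}

read_profile_dir <- function(profiles_dir) {
  files <- sort(list.files(profiles_dir, pattern = "\\.hmm$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no profiles in ", profiles_dir, call. = FALSE)
  profiles <- purrr::map(files, read_profile)
  names(profiles) <- vapply(profiles, function(p) p$label, character(1))
  profiles
}

#' Classify a proteome FASTA against a profile directory
#'
#' @param proteome_path Proteome FASTA.
#' @param profiles_dir Directory of `.hmm` profiles.
#' @param out_path Output calls TSV.
#' @param evalue_threshold Assignment threshold (default 1e-20).
#' @param dbsize Optional database-size override.
#' @return The consolidated calls tibble, invisibly.
#' @export
cmd_classify <- function(proteome_path, profiles_dir, out_path,
                         evalue_threshold = 1e-20, dbsize = NULL) {
  proteome <- read_fasta(proteome_path)
  profiles <- read_profile_dir(profiles_dir)
  calls <- classify_sequences(proteome, profiles,
                              evalue_threshold = evalue_threshold,
                              dbsize = dbsize)
  calls <- dplyr::arrange(calls, .data$taxon, .data$id)
  write_calls(calls, out_path)
  invisible(calls)
}

#' Reconstruct dated events from calls and a species tree
#'
#' @param calls_path Calls TSV from [cmd_classify()] (or a calls tibble).
#' @param tree_path Newick chronogram (or a `phylo`).
#' @param matrix_out,events_out Output TSV paths.
#' @param root_age Optional root age override (Myr).
#' @return The events tibble, invisibly.
#' @export
cmd_events <- function(calls_path, tree_path, matrix_out, events_out,
                       root_age = NULL) {
  calls <- if (is.data.frame(calls_path)) calls_path
           else readr::read_tsv(calls_path, show_col_types = FALSE)
  tree <- if (inherits(tree_path, "phylo")) with_node_ages(tree_path, root_age)
          else read_species_tree(tree_path, root_age)
  pm <- build_matrix(calls, taxa = tree$tip.label)
  events <- dollo_events(pm, tree)
  write_presence(pm, matrix_out)
  write_events(events, events_out)
  invisible(events)
}

#' Report arrangements for gene pairs
#'
#' @param loci_path BED-like gene table (path or tibble).
#' @param pairs Tibble with `gene_a`, `gene_b` columns.
#' @param out_path Optional output TSV.
#' @return Tibble of [detect_synteny()] rows.
#' @export
cmd_synteny <- function(loci_path, pairs, out_path = NULL) {
  loci <- if (is.data.frame(loci_path)) loci_path else read_gene_table(loci_path)
  res <- dplyr::bind_rows(purrr::map2(pairs$gene_a, pairs$gene_b, function(a, b) {
    detect_synteny(loci, a, b)
  }))
  if (!is.null(out_path)) readr::write_tsv(res, out_path)
  res
}

#' Emit a synthetic fixture bundle
#'
#' Simulates a gain/loss history, generates the matching proteome and a
#' gene table with planted arrangements, and writes the whole bundle:
#' `tree.nwk`, `proteome.fasta`, `alignments/` (curated-style per-orthogroup
#' aligned FASTA), `presence.tsv`, `events.tsv`, `membership.tsv`,
#' `loci.tsv` and a `summary.json`.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param cfg Optional [sim_config()] overriding the seed.
#' @return Invisible list with the in-memory truth, proteome and paths.
#' @export
cmd_simulate <- function(out_dir, seed = 1, cfg = sim_config(seed = seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_history(cfg)
  profiles <- reference_profiles(seed = cfg$seed)
  prot <- generate_proteome(truth, profiles, cfg)
  planted <- tibble(
    gene_a = c("DNase1L2", "Uox", "Tafazzin"),
    gene_b = c("DNase1", "DNase2b", "DNase1L1"),
    arrangement = c("TANDEM_SAME_STRAND", "HEAD_TO_HEAD", "HEAD_TO_HEAD"),
    distance = c(630, 200, 400), intervening = c(0L, 0L, 0L))
  loci <- generate_gene_table(planted)

  ape::write.tree(cfg$tree, file.path(out_dir, "tree.nwk"))
  write_fasta(prot$proteome, file.path(out_dir, "proteome.fasta"))
  aln_dir <- file.path(out_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  purrr::iwalk(reference_alignments(), function(aln, label) {
    write_fasta(aln, file.path(aln_dir, paste0(label, ".fasta")))
  })
  write_presence(truth$presence, file.path(out_dir, "presence.tsv"))
  write_events(truth$events, file.path(out_dir, "events.tsv"))
  readr::write_tsv(prot$membership, file.path(out_dir, "membership.tsv"))
  write_gene_table(loci, file.path(out_dir, "loci.tsv"))
  summary <- list(
    seed = cfg$seed, loss_rate = cfg$loss_rate,
    taxa = length(cfg$tree$tip.label),
    orthogroups = length(cfg$gain_branches),
    members = sum(!is.na(prot$membership$orthogroup)),
    decoys = sum(is.na(prot$membership$orthogroup)),
    losses = sum(truth$events$event == "loss"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(truth = truth, proteome = prot, out_dir = out_dir))
}
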