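#' Synthetic data generation
#'
#' Ground-truthed inputs for every pipeline stage without downloads:
#' gene-family histories simulated on a dated tree (single gain followed by
#' Poisson losses), proteomes whose orthogroup members are sampled from the
#' bundled synthetic profiles with implanted diagnostic motifs plus
#' composition-matched decoys, and gene tables with planted synteny.
#'
#' The bundled orthogroup consensus sequences are synthetic: two family
#' ancestors diversified per orthogroup, carrying the diagnostic cysteine
#' pairs, PLD triads, and the family-1 loop whose deletion distinguishes
#' DNase1L2. They emulate the structure of the real families, not their
#' actual sequences.
#'
#' @name synthetic_data
NULL

ORTHO_FAMILY <- c(DNase1 = 1, DNase1L1 = 1, DNase1L1L = 1, DNase1L2 = 1,
                  DNase1L3 = 1, DNase1L4 = 1, `DNase1L4-2` = 1,
                  DNase1L5 = 1, DNase2 = 2, DNase2b = 2)

FAM1_LEN <- 240L
FAM2_LEN <- 340L
FAM1_PAIR_POS <- list("C4-C32" = c(4L, 32L), "C101-C104" = c(101L, 104L),
                      "C173-C209" = c(173L, 209L))
FAM1_LOOP <- 95:109 # fifteen-residue loop (spans C101-C104) absent in DNase1L2
FAM2_TRIAD_POS <- c(H1 = 120L, K1 = 122L, H2 = 290L, K2 = 292L)
FAM2_PAIR_POS <- list(P1 = c(60L, 75L), P2 = c(150L, 180L),
                      P3 = c(230L, 260L), P4 = c(310L, 325L))

sample_non_cys <- function(n) {
  aa <- setdiff(AA20, "C")
  p <- aa_background()[aa]
  sample(aa, n, replace = TRUE, prob = p / sum(p))
}

# per-orthogroup consensus sequences and reference positions (deterministic)
orthogroup_blueprints <- function() {
  if (!is.null(.dnaserep_cache$blueprints)) return(.dnaserep_cache$blueprints)
  exp_tab <- orthogroup_expectations()
  bps <- withr::with_seed(8104729L, {
    anc1 <- sample_non_cys(FAM1_LEN)
    for (p in unlist(FAM1_PAIR_POS)) anc1[p] <- "C"
    anc2 <- sample_non_cys(FAM2_LEN)
    for (p in unlist(FAM2_PAIR_POS)) anc2[p] <- "C"
    anc2[FAM2_TRIAD_POS["H1"]] <- "H"; anc2[FAM2_TRIAD_POS["K1"]] <- "K"
    anc2[FAM2_TRIAD_POS["H2"]] <- "H"; anc2[FAM2_TRIAD_POS["K2"]] <- "K"
    anc2[FAM2_TRIAD_POS["H1"] + 1L] <- "S"
    anc2[FAM2_TRIAD_POS["H2"] + 1L] <- "S"

    purrr::map(dnase_orthogroups(), function(label) {
      fam <- ORTHO_FAMILY[[label]]
      if (fam == 1) {
        cons <- anc1
        pair_pos <- FAM1_PAIR_POS
        if (label == "DNase1L2") {
          cons <- cons[-FAM1_LOOP]
          shift <- function(p) p - sum(FAM1_LOOP < p) # positions after the loop
          pair_pos <- purrr::map(FAM1_PAIR_POS[c("C4-C32", "C173-C209")],
                                 function(pp) vapply(pp, shift, integer(1)))
        }
        expected <- exp_tab$cys_pairs[[match(label, exp_tab$label)]]
        kept <- intersect(names(pair_pos), expected)
        dropped <- setdiff(names(pair_pos), expected)
        reserved <- unlist(pair_pos[kept], use.names = FALSE)
        free <- setdiff(seq_along(cons), unlist(pair_pos, use.names = FALSE))
        mut <- free[stats::runif(length(free)) < 0.40]
        cons[mut] <- sample_non_cys(length(mut))
        for (pp in pair_pos[dropped]) cons[pp] <- "S"
        ref_pos <- do.call(c, unname(purrr::imap(pair_pos, function(pp, nm) {
          setNames(pp, cys_pair_definitions()[[nm]])
        })))
      } else {
        cons <- anc2
        pair_pos <- FAM2_PAIR_POS
        triads <- FAM2_TRIAD_POS
        kept_pairs <- if (label == "DNase2b") names(pair_pos)
                      else setdiff(names(pair_pos), "P4")
        reserved <- c(unlist(pair_pos[kept_pairs], use.names = FALSE),
                      triads, triads[c("H1", "H2")] + 1L)
        free <- setdiff(seq_along(cons),
                        c(unlist(pair_pos, use.names = FALSE), triads,
                          triads[c("H1", "H2")] + 1L))
        mut <- free[stats::runif(length(free)) < 0.35]
        cons[mut] <- sample_non_cys(length(mut))
        if (label == "DNase2") for (p in pair_pos[["P4"]]) cons[p] <- "S"
        ref_pos <- c(triads,
                     do.call(c, unname(purrr::imap(
                       pair_pos[kept_pairs],
                       function(pp, nm) {
                         setNames(pp, cys_pair_definitions()[[nm]])
                       }))))
      }
      list(label = label, family = fam,
           consensus = paste(cons, collapse = ""),
           reference_positions = ref_pos,
           reserved = sort(unique(as.integer(reserved))))
    })
  })
  names(bps) <- dnase_orthogroups()
  .dnaserep_cache$blueprints <- bps
  bps
}

#' Bundled curated-style orthogroup alignments
#'
#' One ungapped alignment per orthogroup: the synthetic consensus (row
#' `<label>_ref`) plus `n_per_group - 1` orthologs diverged from it at the
#' given per-site substitution rate, with diagnostic positions held fixed.
#' Deterministic: the same arguments always return the same alignments.
#'
#' @param n_per_group Rows per alignment (default 12, within the 10-20 range
#'   used for real curated sets).
#' @param divergence Per-site substitution probability (default 0.12).
#' @return Named list of [aa_alignment()] objects.
#' @export
reference_alignments <- function(n_per_group = 12, divergence = 0.12) {
  bps <- orthogroup_blueprints()
  withr::with_seed(4256233L, {
    purrr::map(bps, function(bp) {
      cons <- strsplit(bp$consensus, "")[[1]]
      free <- setdiff(seq_along(cons), bp$reserved)
      rows <- vapply(seq_len(n_per_group - 1), function(i) {
        s <- cons
        mut <- free[stats::runif(length(free)) < divergence]
        s[mut] <- sample_non_cys(length(mut))
        paste(s, collapse = "")
      }, character(1))
      aa_alignment(tibble(
        id = c(paste0(bp$label, "_ref"),
               paste0(bp$label, "_ortho", seq_len(n_per_group - 1))),
        aligned = c(bp$consensus, rows)))
    })
  })
}

#' Bundled calibrated orthogroup profiles
#'
#' Builds and calibrates one profile HMM per orthogroup from
#' [reference_alignments()], with reference maps covering the diagnostic
#' cysteine pairs and PLD triads.
#'
#' @param seed Calibration seed.
#' @param n_samples Background samples per calibration (default 200).
#' @param ... Passed to [build_profile()].
#' @return Named list of calibrated `profile_hmm`s.
#' @export
reference_profiles <- function(seed = 1, n_samples = 200, ...) {
  alns <- reference_alignments()
  bps <- orthogroup_blueprints()
  out <- purrr::imap(alns, function(msa, label) {
    hmm <- suppressWarnings(build_profile(
      msa, label, reference = paste0(label, "_ref"),
      reference_positions = bps[[label]]$reference_positions, ...))
    calibrate_profile(hmm, n_samples = n_samples,
                      seed = (seed %% 1000000L) * 100L +
                        match(label, dnase_orthogroups()))
  })
  names(out) <- dnase_orthogroups()
  out
}

# terminal implants per orthogroup: signal/acidic prefix + C-terminal class
implant_table <- function() {
  signal_prefix <- "MKWLALLLVALA"   # hydrophobic core after a K
  acidic_prefix <- "MDEDESDETQ"     # blocks the signal-peptide heuristic
  suffix <- c(
    DNase1 = "QTGSDNSATGQS", DNase1L2 = "QTGSDNSATGQS",          # NONE
    DNase1L1 = "SAASGSALLVVLLAVVL",                              # GPI
    DNase1L1L = "QTSDNQGSTNEL",                                  # EL
    DNase1L3 = "SSKRSKKSKKRK", DNase1L4 = "SSKRSKKSKKRK",        # BASIC
    `DNase1L4-2` = "SSKRSKKSKKRK",
    DNase1L5 = "CSSCDCNNCKCESC",                                 # SMB
    DNase2 = "QTGSDNSATGQS", DNase2b = "QTGSDNSATGQS")           # NONE
  exp_tab <- orthogroup_expectations()
  tibble(label = exp_tab$label,
         prefix = ifelse(exp_tab$signal_peptide, signal_prefix, acidic_prefix),
         suffix = unname(suffix[exp_tab$label]))
}

#' The bundled chordate chronogram
#'
#' A 21-leaf chordate species tree with round TimeTree-style node ages
#' (Myr), shipped as a Newick fixture. Internal nodes are labelled with
#' clade names (Vertebrata, Gnathostomata, Euteleostomi, Amniota, Aves, ...)
#' so that gain/loss events report readable branches.
#'
#' @return An `ape::phylo` with an `ages` attribute.
#' @export
default_chordate_tree <- function() {
  path <- system.file("extdata", "chordate_chronogram.nwk",
                      package = "dnaserep", mustWork = TRUE)
  read_species_tree(path)
}

#' Default gain branches of the ten orthogroups
#'
#' The branch (named by its child node) on which each orthogroup arose:
#' DNase1 and DNase2b predate chordates (root); DNase2, DNase1L3 and
#' DNase1L1L arose on the vertebrate stem; DNase1L4 and DNase1L5 on the
#' jawed-vertebrate stem; DNase1L1 on the bony-vertebrate stem; DNase1L4-2
#' in neopterygian fishes; DNase1L2 on the amniote stem.
#'
#' @return Named character vector (orthogroup -> node label).
#' @export
default_gain_branches <- function() {
  c(DNase1 = "Chordata", DNase2b = "Chordata",
    DNase2 = "Vertebrata", DNase1L3 = "Vertebrata",
    DNase1L1L = "Vertebrata",
    DNase1L4 = "Gnathostomata", DNase1L5 = "Gnathostomata",
    DNase1L1 = "Euteleostomi", `DNase1L4-2` = "Neopterygii",
    DNase1L2 = "Amniota")
}

clade_tips <- function(tree, label) {
  v <- node_by_label(tree, label)
  ntip <- length(tree$tip.label)
  if (v <= ntip) return(tree$tip.label[v])
  tree$tip.label[descendant_tips(tree)[[v]]]
}

#' The known chordate DNase repertoire
#'
#' The presence/absence pattern of the ten orthogroups across the bundled
#' 21-species chronogram, as established for the real repertoire: DNase1
#' everywhere; DNase2 lost in birds; DNase1L1L lost independently in birds
#' and placentals; DNase1L1 absent from birds; DNase1L4 and DNase1L5 lost
#' in amniotes (DNase1L5 also in neopterygians); DNase1L4-2 restricted to
#' bony fishes; DNase2b lost in the lamprey, snake and monotreme lineages;
#' DNase1L2 confined to amniotes.
#'
#' @param tree The chronogram (default [default_chordate_tree()]).
#' @return A [presence_matrix()].
#' @export
chordate_repertoire <- function(tree = default_chordate_tree()) {
  all_tips <- tree$tip.label
  ct <- function(lab) clade_tips(tree, lab)
  sets <- list(
    DNase1 = all_tips,
    DNase1L1 = setdiff(ct("Euteleostomi"), ct("Aves")),
    DNase1L1L = setdiff(ct("Vertebrata"), c(ct("Aves"), ct("Placentalia"))),
    DNase1L2 = ct("Amniota"),
    DNase1L3 = setdiff(ct("Vertebrata"), ct("Actinopterygii")),
    DNase1L4 = setdiff(ct("Gnathostomata"), ct("Amniota")),
    `DNase1L4-2` = setdiff(ct("Neopterygii"), "Oryzias_latipes"),
    DNase1L5 = setdiff(ct("Gnathostomata"),
                       c(ct("Neopterygii"), ct("Amniota"))),
    DNase2 = setdiff(ct("Vertebrata"), ct("Aves")),
    DNase2b = setdiff(all_tips, c("Petromyzon_marinus", "Python_bivittatus",
                                  "Ornithorhynchus_anatinus")))
  cols <- purrr::map(sets[dnase_orthogroups()], function(s) all_tips %in% s)
  presence_matrix(dplyr::bind_cols(tibble(taxon = all_tips),
                                   as_tibble(cols, .name_repair = "minimal")))
}

#' Simulation configuration
#'
#' @param seed Master seed; every downstream draw derives from it.
#' @param tree Dated species tree.
#' @param gain_branches Named character vector (orthogroup -> child node
#'   label of the gain branch).
#' @param loss_rate Loss events per Myr per lineage (default 5e-4, giving on
#'   the order of two losses per orthogroup on the bundled chronogram).
#' @param members_per_cell Members generated per present (taxon, orthogroup)
#'   cell.
#' @param decoys_per_taxon Shuffled decoy sequences per taxon.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, tree = default_chordate_tree(),
                       gain_branches = default_gain_branches(),
                       loss_rate = 5e-4, members_per_cell = 1L,
                       decoys_per_taxon = 2L) {
  stopifnot(loss_rate >= 0, is.finite(loss_rate), members_per_cell >= 1)
  structure(list(seed = as.integer(seed), tree = with_node_ages(tree),
                 gain_branches = gain_branches, loss_rate = loss_rate,
                 members_per_cell = as.integer(members_per_cell),
                 decoys_per_taxon = as.integer(decoys_per_taxon)),
            class = "sim_config")
}

#' Simulate a gain/loss history
#'
#' For each orthogroup, presence propagates from its configured gain branch;
#' losses arise as a Poisson process (rate x branch length in Myr) on
#' descendant branches, and a lost lineage stays lost. Each realised loss is
#' flagged `identifiable` when Dollo parsimony can in principle recover its
#' exact branch: the loss parent retains at least one present leaf and lies
#' at or below the realised most recent common ancestor of the present
#' leaves.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_truth` list: `presence` ([presence_matrix()]), `events`
#'   tibble (gains and losses with ages and `identifiable`), and the config.
#' @export
simulate_history <- function(cfg) {
  tree <- cfg$tree
  ages <- attr(tree, "ages")
  ntip <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  kids <- purrr::map(seq_len(ntip + tree$Nnode), function(v) {
    tree$edge[tree$edge[, 1] == v, 2]
  })
  edge_len <- setNames(tree$edge.length, tree$edge[, 2])

  bad <- setdiff(cfg$gain_branches, c(tree$tip.label, tree$node.label))
  if (length(bad) > 0) {
    stop("gain branch not in tree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  truth <- withr::with_seed(cfg$seed, {
    purrr::imap(cfg$gain_branches, function(gain_label, g) {
      v0 <- node_by_label(tree, gain_label)
      present <- rep(FALSE, ntip)
      losses <- list()
      walk <- function(v) {
        if (v <= ntip) { present[v] <<- TRUE; return(invisible()) }
        for (ch in kids[[v]]) {
          n_loss <- stats::rpois(1, cfg$loss_rate * edge_len[[as.character(ch)]])
          if (n_loss >= 1) {
            losses[[length(losses) + 1]] <<- c(parent = v, child = ch)
          } else {
            walk(ch)
          }
        }
      }
      walk(v0)
      list(gain_node = v0, present = present, losses = losses)
    })
  })

  events <- purrr::imap(truth, function(tr, g) {
    present_tips <- which(tr$present)
    root <- ntip + 1L
    parent_of <- integer(ntip + tree$Nnode)
    parent_of[tree$edge[, 2]] <- tree$edge[, 1]
    gain <- tibble(
      orthogroup = g, event = "gain",
      parent = if (tr$gain_node == root) NA_character_
               else node_label(tree, parent_of[tr$gain_node]),
      child = node_label(tree, tr$gain_node),
      older = if (tr$gain_node == root) NA_real_
              else ages[parent_of[tr$gain_node]],
      younger = ages[tr$gain_node],
      identifiable = TRUE)
    if (length(tr$losses) == 0) return(gain)
    mrca_tips <- present_tips
    mrca <- if (length(mrca_tips) == 0) NA_integer_
            else if (length(mrca_tips) == 1) mrca_tips
            else ape::getMRCA(tree, mrca_tips)
    loss_rows <- purrr::map(tr$losses, function(l) {
      p <- l[["parent"]]; v <- l[["child"]]
      p_tips <- desc[[p]]
      ident <- !is.na(mrca) &&
        any(p_tips %in% present_tips) &&
        all(p_tips %in% desc[[mrca]])
      tibble(orthogroup = g, event = "loss",
             parent = node_label(tree, p), child = node_label(tree, v),
             older = ages[p], younger = ages[v], identifiable = ident)
    })
    dplyr::bind_rows(c(list(gain), loss_rows))
  })

  mat <- vapply(truth, function(tr) tr$present, logical(ntip))
  pm <- presence_matrix(dplyr::bind_cols(
    tibble(taxon = tree$tip.label),
    as_tibble(as.data.frame(mat), .name_repair = "minimal")))
  structure(list(presence = pm, events = dplyr::bind_rows(events),
                 config = cfg),
            class = "sim_truth")
}

#' Generate a synthetic proteome from a simulated history
#'
#' For every present (taxon, orthogroup) cell, samples member sequences from
#' the orthogroup's profile, repairs/implants the diagnostic residues at the
#' reference columns, and attaches the orthogroup's terminal implants
#' (signal or acidic N-terminal peptide; GPI / basic / SMB / EL / neutral
#' C-terminal peptide). Adds residue-shuffled, composition-matched decoys
#' per taxon. Deterministic given the config seed.
#'
#' @param truth A `sim_truth` from [simulate_history()].
#' @param profiles Named list of profiles covering every orthogroup present
#'   in the truth (default [reference_profiles()] built with the config
#'   seed).
#' @param cfg The [sim_config()] (default: the one inside `truth`).
#' @return List with `proteome` (tibble `id`, `taxon`, `sequence`) and
#'   `membership` (tibble `id`, `taxon`, `orthogroup`; decoys have
#'   `orthogroup = NA`).
#' @export
generate_proteome <- function(truth, profiles = NULL, cfg = truth$config) {
  if (is.null(profiles)) profiles <- reference_profiles(seed = cfg$seed)
  pm <- truth$presence
  orthogroups <- setdiff(names(pm), "taxon")
  missing <- setdiff(orthogroups, names(profiles))
  if (length(missing) > 0) {
    stop("no profile for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  implants <- implant_table()
  withr::with_seed(cfg$seed + 1L, {
    rows <- list(); members <- list()
    for (t in pm$taxon) {
      taxon_members <- character(0)
      for (g in orthogroups) {
        if (!pm[[g]][pm$taxon == t]) next
        for (m in seq_len(cfg$members_per_cell)) {
          core <- implant_core(profiles[[g]])
          imp <- implants[implants$label == g, ]
          seqstr <- paste0(imp$prefix, core, imp$suffix)
          id <- sprintf("%s|%s|%d", t, g, m)
          rows[[id]] <- tibble(id = id, taxon = t, sequence = seqstr)
          members[[id]] <- tibble(id = id, taxon = t, orthogroup = g)
          taxon_members <- c(taxon_members, seqstr)
        }
      }
      if (cfg$decoys_per_taxon > 0) {
        for (d in seq_len(cfg$decoys_per_taxon)) {
          base <- if (length(taxon_members) > 0) {
            sample(taxon_members, 1)
          } else {
            g <- sample(orthogroups, 1)
            paste0(implant_table()$prefix[1], implant_core(profiles[[g]]))
          }
          shuffled <- paste(sample(strsplit(base, "")[[1]]), collapse = "")
          id <- sprintf("%s|decoy|%d", t, d)
          rows[[id]] <- tibble(id = id, taxon = t, sequence = shuffled)
          members[[id]] <- tibble(id = id, taxon = t,
                                  orthogroup = NA_character_)
        }
      }
    }
    list(proteome = dplyr::bind_rows(rows),
         membership = dplyr::bind_rows(members))
  })
}

# sample a core domain from a profile and guarantee its diagnostic residues:
# every reference column is forced to the profile's consensus residue there
# (repairing both sampling noise and deletions)
implant_core <- function(hmm) {
  smp <- sample_sequence(hmm)
  path <- smp$path
  chars <- strsplit(smp$sequence, "")[[1]]
  emit_rows <- which(path$state %in% c("M", "I"))
  residues <- rep(NA_character_, nrow(path))
  residues[emit_rows] <- chars
  rm <- hmm$reference_map
  for (i in seq_along(rm)) {
    k <- rm[[i]]
    res <- AA20[which.max(hmm$match_em[k, ])]
    row <- which(path$match_state == k & path$state %in% c("M", "D"))
    if (length(row) == 0) next
    path$state[row[1]] <- "M"
    residues[row[1]] <- res
  }
  paste(residues[path$state %in% c("M", "I")], collapse = "")
}

#' Generate a gene table with planted synteny
#'
#' Constructs coordinates so that [detect_synteny()] recovers exactly the
#' planted arrangement, distance and intervening-gene count for each pair.
#' Each pair occupies its own chromosome; filler genes (length 1) are placed
#' strictly inside the intergenic gap.
#'
#' @param planted Tibble with columns `gene_a`, `gene_b`, `arrangement`
#'   (TANDEM_SAME_STRAND / HEAD_TO_HEAD / TAIL_TO_TAIL / UNLINKED),
#'   `distance` (bp; ignored for UNLINKED), and optional `intervening`
#'   (default 0; requires `distance > intervening`).
#' @param gene_length Span of each planted gene (default 1000 bp).
#' @return Gene table tibble (`gene`, `chromosome`, `start`, `end`,
#'   `strand`, `score`).
#' @export
generate_gene_table <- function(planted, gene_length = 1000L) {
  if (!"intervening" %in% names(planted)) planted$intervening <- 0L
  genes <- c(planted$gene_a, planted$gene_b)
  if (anyDuplicated(genes)) {
    stop("contradictory plant: a gene appears twice", call. = FALSE)
  }
  rows <- purrr::pmap(planted, function(gene_a, gene_b, arrangement,
                                        distance, intervening, ...) {
    i <- which(planted$gene_a == gene_a)
    chrom <- paste0("chr", i)
    if (arrangement == "UNLINKED") {
      return(tibble(
        gene = c(gene_a, gene_b), chromosome = c(chrom, paste0(chrom, "b")),
        start = 1000L, end = 1000L + gene_length,
        strand = c("+", "+"), score = 0L))
    }
    if (distance < 0) stop("negative planted distance", call. = FALSE)
    if (intervening > 0 && distance < intervening + 1) {
      stop("distance too small for planted intervening genes", call. = FALSE)
    }
    strands <- switch(arrangement,
                      TANDEM_SAME_STRAND = c("+", "+"),
                      HEAD_TO_HEAD = c("-", "+"),
                      TAIL_TO_TAIL = c("+", "-"),
                      stop("unknown arrangement: ", arrangement, call. = FALSE))
    a_start <- 1000L
    a_end <- a_start + gene_length
    b_start <- a_end + as.integer(distance)
    out <- tibble(gene = c(gene_a, gene_b), chromosome = chrom,
                  start = c(a_start, b_start),
                  end = c(a_end, b_start + gene_length),
                  strand = strands, score = 0L)
    if (intervening > 0) {
      pos <- a_end + floor(seq_len(intervening) * distance / (intervening + 1))
      pos <- pmin(pmax(pos, a_end), b_start - 1L)
      out <- dplyr::bind_rows(out, tibble(
        gene = sprintf("filler_%d_%d", i, seq_len(intervening)),
        chromosome = chrom, start = as.integer(pos),
        end = as.integer(pos + 1L), strand = "+", score = 0L))
    }
    out
  })
  dplyr::bind_rows(rows)
}
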