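test_that("presence matrices build from calls with strict taxon checking", {
  taxa <- c("t1", "t2", "t3")
  empty <- build_matrix(tibble::tibble(taxon = character(),
                                       label = character()), taxa)
  expect_true(all(!as.matrix(empty[, -1])))
  expect_equal(empty$taxon, taxa)

  calls <- tibble::tibble(taxon = c("t1", "t2"),
                          label = c("DNase1", "DNase2"))
  pm <- build_matrix(calls, taxa)
  expect_true(pm$DNase1[1] && pm$DNase2[2])
  expect_equal(sum(as.matrix(pm[, -1])), 2)

  expect_error(build_matrix(tibble::tibble(taxon = "nope", label = "DNase1"),
                            taxa), "absent from")
})

test_that("invertebrates carry only the minimal DNase repertoire", {
  pm <- chordate_repertoire()
  for (t in c("Branchiostoma_floridae", "Ciona_intestinalis")) {
    row <- pm[pm$taxon == t, -1]
    expect_setequal(names(row)[unlist(row)], c("DNase1", "DNase2b"))
  }
})

test_that("Dollo handles the degenerate presence patterns", {
  tree <- read_species_tree("((a:1,b:1)ab:1,(c:1,d:1)cd:1)r;")
  all_present <- presence_matrix(tibble::tibble(
    taxon = c("a", "b", "c", "d"), G = rep(TRUE, 4)))
  ev <- suppressWarnings(dollo_events(all_present, tree))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event, "gain")
  expect_true(is.na(ev$older)) # root gain: unbounded older side

  one_absent <- presence_matrix(tibble::tibble(
    taxon = c("a", "b", "c", "d"), G = c(TRUE, TRUE, TRUE, FALSE)))
  ev2 <- dollo_events(one_absent, tree)
  losses <- ev2[ev2$event == "loss", ]
  expect_equal(nrow(losses), 1)
  expect_equal(losses$child, "d")

  none <- presence_matrix(tibble::tibble(taxon = c("a", "b", "c", "d"),
                                         G = rep(FALSE, 4)))
  expect_warning(ev3 <- dollo_events(none, tree), "absent everywhere")
  expect_equal(nrow(ev3), 0)

  stray <- presence_matrix(tibble::tibble(taxon = "zz", G = TRUE))
  expect_error(dollo_events(stray, tree), "not in tree")
})

test_that("the chordate repertoire reproduces the known gain/loss history", {
  tree <- default_chordate_tree()
  ev <- dollo_events(chordate_repertoire(tree), tree)

  d2 <- ev[ev$orthogroup == "DNase2" & ev$event == "loss", ]
  expect_equal(nrow(d2), 1)
  expect_equal(d2$child, "Aves")

  l1l <- ev[ev$orthogroup == "DNase1L1L" & ev$event == "loss", ]
  expect_setequal(l1l$child, c("Aves", "Placentalia"))

  gain1l2 <- ev[ev$orthogroup == "DNase1L2" & ev$event == "gain", ]
  expect_equal(gain1l2$child, "Amniota")
  expect_true(gain1l2$older > 330 && gain1l2$younger < 330)

  gain1l1 <- ev[ev$orthogroup == "DNase1L1" & ev$event == "gain", ]
  expect_equal(gain1l1$child, "Euteleostomi")
  expect_true(gain1l1$older > 450 && gain1l1$younger < 450)
})

test_that("loss counts match the exhaustive Dollo minimum on random trees", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    tree <- with_node_ages(ape::rtree(n))
    k <- sample(seq_len(n - 1), 1)
    present <- sample(tree$tip.label, k)
    pm <- presence_matrix(tibble::tibble(taxon = tree$tip.label,
                                         G = tree$tip.label %in% present))
    ev <- dollo_events(pm, tree)
    expect_equal(sum(ev$event == "loss"),
                 oracle_dollo_losses(tree, present),
                 info = paste("rep", rep))
  }
})

test_that("event intervals are proper and bounded by the root age", {
  tree <- default_chordate_tree()
  ev <- dollo_events(chordate_repertoire(tree), tree)
  root_age <- max(attr(tree, "ages"))
  finite <- ev[!is.na(ev$older), ]
  expect_true(all(finite$older > finite$younger))
  expect_true(all(finite$older <= root_age))
  expect_true(all(ev$younger >= 0))
})

test_that("inferred events forward-simulate back to the input matrix", {
  tree <- default_chordate_tree()
  pm <- chordate_repertoire(tree)
  ev <- dollo_events(pm, tree)
  back <- presence_from_events(ev, tree)
  expect_equal(as.data.frame(back[, names(pm)]), as.data.frame(pm))
})

test_that("duplication intervals date tandem paralogs", {
  tree <- default_chordate_tree()
  ev <- dollo_events(chordate_repertoire(tree), tree)

  t1l1l <- duplication_interval(ev, "DNase1L1L", "DNase1L1")
  expect_equal(c(t1l1l$older, t1l1l$younger), c(473, 435))
  expect_true(abs(t1l1l$midpoint - 450) < 25)

  t1 <- duplication_interval(ev, "DNase1", "DNase1L2")
  expect_equal(c(t1$older, t1$younger), c(352, 319))
  expect_true(abs(t1$midpoint - 330) < 15)

  expect_error(duplication_interval(ev, "DNase1", "NotAGene"), "no gain")

  # a child gained on a terminal branch inherits that branch's interval:
  # ages here are r = 3, ab = 2, a = 1 (root age = deepest tip)
  tr2 <- read_species_tree("((a:1,b:2)ab:1,c:3)r;")
  pm2 <- presence_matrix(tibble::tibble(
    taxon = c("a", "b", "c"), P = c(TRUE, TRUE, TRUE),
    Q = c(TRUE, FALSE, FALSE)))
  ev2 <- dollo_events(pm2, tr2)
  q <- duplication_interval(ev2, "P", "Q")
  expect_equal(c(q$older, q$younger), c(2, 1))
})

test_that("synteny arrangements follow strand and coordinate geometry", {
  loci <- tibble::tibble(
    gene = c("A", "B", "C", "D", "E"),
    chromosome = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    start = c(1000L, 3630L, 6000L, 100L, 2500L),
    end = c(2000L, 4630L, 7000L, 900L, 2600L),
    strand = c("+", "+", "-", "+", "+"))

  tandem <- detect_synteny(loci, "A", "B")
  expect_equal(tandem$arrangement, "TANDEM_SAME_STRAND")
  expect_equal(tandem$distance, 1630)
  expect_equal(tandem$intervening, 1) # E sits in the gap

  t2t <- detect_synteny(loci, "B", "C")
  expect_equal(t2t$arrangement, "TAIL_TO_TAIL")

  h2h <- detect_synteny(loci, "C", "B")   # minus-strand gene downstream? no:
  # order is by coordinate, B (left, +) then C (right, -): convergent
  expect_equal(h2h$arrangement, "TAIL_TO_TAIL")

  unl <- detect_synteny(loci, "A", "D")
  expect_equal(unl$arrangement, "UNLINKED")
  expect_equal(unl$distance, -1)

  # symmetry in gene order
  ab <- detect_synteny(loci, "A", "B"); ba <- detect_synteny(loci, "B", "A")
  expect_equal(ab$arrangement, ba$arrangement)
  expect_equal(ab$distance, ba$distance)

  over <- tibble::tibble(gene = c("X", "Y"), chromosome = "c",
                         start = c(0L, 500L), end = c(1000L, 1500L),
                         strand = c("+", "+"))
  expect_warning(res <- detect_synteny(over, "X", "Y"), "overlap")
  expect_equal(res$distance, 0)

  expect_error(detect_synteny(loci, "A", "nope"), "not in table")
})

test_that("head-to-head means divergent strands with minus gene upstream", {
  loci <- generate_gene_table(tibble::tibble(
    gene_a = "Uox", gene_b = "DNase2b", arrangement = "HEAD_TO_HEAD",
    distance = 200))
  res <- detect_synteny(loci, "DNase2b", "Uox")
  expect_equal(res$arrangement, "HEAD_TO_HEAD")
  expect_equal(res$distance, 200)
})

test_that("the bundled example loci show the published arrangements", {
  path <- system.file("extdata", "example_loci.tsv", package = "dnaserep")
  loci <- read_gene_table(path)
  chick <- detect_synteny(loci, "GgDNase1L2", "GgDNase1")
  expect_equal(chick$arrangement, "TANDEM_SAME_STRAND")
  expect_equal(chick$distance, 630)
  expect_equal(detect_synteny(loci, "DNase2b", "Uox")$arrangement,
               "HEAD_TO_HEAD")
  expect_equal(detect_synteny(loci, "DNase1L1", "Tafazzin")$arrangement,
               "HEAD_TO_HEAD")
})
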