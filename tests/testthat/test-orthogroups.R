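smap2 <- function(genes_g, genes_q) {
  data.frame(gene = c(genes_g, genes_q),
             species = c(rep("gambiae", length(genes_g)),
                         rep("quad", length(genes_q))),
             stringsAsFactors = FALSE)
}

test_that("basic clade patterns reconcile to the expected events", {
  # perfect 1:1 ortholog pair
  tr <- ape::read.tree(text = "(G1,Q1)100;")
  ogs <- delineate_orthogroups(tr, smap2("G1", "Q1"))
  expect_length(ogs, 1)
  expect_equal(ogs[[1]]$gains_a + ogs[[1]]$gains_b +
                 ogs[[1]]$losses_a + ogs[[1]]$losses_b, 0)

  # supported duplication in one species
  tr <- ape::read.tree(text = "(((G1,G2)95,Q1)98);")
  ogs <- delineate_orthogroups(tr, smap2(c("G1", "G2"), "Q1"))
  expect_length(ogs, 1)
  expect_equal(ogs[[1]]$gains_a, 1)
  expect_equal(ogs[[1]]$losses_b, 0)

  # unpaired single-species leaf: ancestral present, lost in the other
  ogs <- delineate_orthogroups("Q9", smap2(character(0), "Q9"),
                               species = c("gambiae", "quad"))
  expect_length(ogs, 1)
  expect_equal(ogs[[1]]$losses_a, 1)
  expect_equal(ogs[[1]]$gains_b, 0)

  expect_error(delineate_orthogroups(tr, smap2("G1", "Q1")), "unmapped leaf")
})

test_that("unsupported clades are split and non-monophyletic duplicates descend", {
  # the OG is the outer supported clade; inner supports are not part of
  # the definition
  tr <- ape::read.tree(text = "(((G1,G2)50,Q1)100);")
  ogs <- delineate_orthogroups(tr, smap2(c("G1", "G2"), "Q1"))
  expect_length(ogs, 1)
  expect_equal(ogs[[1]]$gains_a, 1)

  # an unsupported outer clade is resolved by descending
  tr <- ape::read.tree(text = "(((G1,G2)95,Q1)50);")
  ogs <- delineate_orthogroups(tr, smap2(c("G1", "G2"), "Q1"))
  expect_length(ogs, 2)

  # (G1,(G2,Q1)): G genes not monophyletic; resolves to G1 + a 1:1 pair
  tr <- ape::read.tree(text = "((G1,(G2,Q1)100)100);")
  ogs <- delineate_orthogroups(tr, smap2(c("G1", "G2"), "Q1"))
  expect_length(ogs, 2)
  sizes <- sort(vapply(ogs, function(o)
    length(o$members_a) + length(o$members_b), integer(1)))
  expect_equal(sizes, c(1L, 2L))
})

test_that("every leaf lands in exactly one OG and thresholds only split", {
  set.seed(11)
  # trees with varied supports exercise the threshold
  nwk <- "(((G1,G2)92,(Q1,Q2)85)95,((G3,Q3)88,(G4,Q4)97)91);"
  tr <- ape::read.tree(text = nwk)
  map <- smap2(c("G1", "G2", "G3", "G4"), c("Q1", "Q2", "Q3", "Q4"))
  sizes_at <- function(th) {
    ogs <- delineate_orthogroups(tr, map, support_threshold = th)
    members <- unlist(lapply(ogs, function(o) c(o$members_a, o$members_b)))
    expect_setequal(members, map$gene)       # partition property
    expect_equal(anyDuplicated(members), 0)
    length(ogs)
  }
  n70 <- sizes_at(70); n86 <- sizes_at(86); n96 <- sizes_at(96)
  expect_true(n70 <= n86)
  expect_true(n86 <= n96)
})

test_that("simulated forests are reconciled exactly to the recorded events", {
  sim <- simulate_gene_trees(n_OGs = 120, p_gain = 0.3, p_loss = 0.2, seed = 5)
  ogs <- delineate_forest(sim$trees, sim$species_map)
  expect_length(ogs, length(sim$truth))
  for (i in seq_along(ogs)) {
    expect_setequal(ogs[[i]]$members_a, sim$truth[[i]]$members_a)
    expect_setequal(ogs[[i]]$members_b, sim$truth[[i]]$members_b)
    expect_equal(ogs[[i]]$gains_a, sim$truth[[i]]$gains_a)
    expect_equal(ogs[[i]]$gains_b, sim$truth[[i]]$gains_b)
    expect_equal(ogs[[i]]$losses_a, sim$truth[[i]]$losses_a)
    expect_equal(ogs[[i]]$losses_b, sim$truth[[i]]$losses_b)
  }
})

test_that("repertoire summary enforces the gain/loss bookkeeping identity", {
  og11 <- list(members_a = "G1", members_b = "Q1", ancestral_copies = 1L,
               gains_a = 0L, gains_b = 0L, losses_a = 0L, losses_b = 0L)
  summ <- summarize_repertoire(list(OR = list(og11)))
  expect_equal(summ$count_a[summ$family == "OR"], 1)
  expect_equal(summ$n_OGs[summ$family == "OR"], 1)

  ten <- rep(list(og11), 10)
  summ <- summarize_repertoire(list(OR = ten))
  expect_equal(summ$count_a[summ$family == "total"], 10)
  expect_equal(summ$count_b[summ$family == "total"], 10)

  sim <- simulate_gene_trees(n_OGs = 60, p_gain = 0.4, p_loss = 0.3, seed = 9)
  ogs <- delineate_forest(sim$trees, sim$species_map)
  summ <- summarize_repertoire(list(fam = ogs))
  tru_gains_a <- sum(vapply(sim$truth, function(t) t$gains_a, numeric(1)))
  expect_equal(summ$gains_a[summ$family == "fam"], tru_gains_a)
  # identity: counts reconstruct from MRCA + gains - losses
  r <- summ[summ$family == "fam", ]
  expect_equal(r$count_a, r$n_OGs + r$gains_a - r$losses_a)
  expect_equal(r$count_b, r$n_OGs + r$gains_b - r$losses_b)

  bad <- og11; bad$gains_a <- 5L
  expect_error(summarize_repertoire(list(x = list(bad))), "inconsistent")
})

test_that("newick forests round-trip through files including one-leaf trees", {
  sim <- simulate_gene_trees(n_OGs = 30, p_gain = 0.3, p_loss = 0.3, seed = 2)
  path <- tempfile(fileext = ".nwk")
  writeLines(vapply(sim$trees, function(t) {
    if (is.character(t)) paste0("(", t, ");") else
      ape::write.tree(t)
  }, character(1)), path)
  trees <- read_gene_trees(path)
  ogs <- delineate_forest(trees, sim$species_map)
  expect_length(ogs, 30)
  summ <- summarize_repertoire(list(all = ogs))
  expect_equal(summ$n_OGs[1], 30)
})
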