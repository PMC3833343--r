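test_that("prepare_pair validates and drops gap and stop columns", {
  p <- prepare_pair("ATG", "ATG")
  expect_equal(p$n_codons, 1)
  expect_equal(p$codons_a, "ATG")

  p <- prepare_pair("ATG---AAA", "ATGCCCAAA")
  expect_equal(p$n_codons, 2)
  expect_equal(p$dropped$reason, "gap")
  expect_equal(p$pos_a, c(1, 2))        # reference skips its own gap codon

  p <- prepare_pair("ATGTAA", "ATGTAA")
  expect_equal(p$n_codons, 1)
  expect_equal(p$dropped$reason, "stop")

  expect_error(prepare_pair("ATG", "ATGAAA"), "equal length")
  expect_error(prepare_pair("ATGA", "ATGA"), "multiple of 3")
  expect_error(prepare_pair("ATX", "ATG"), "may only contain")
})

test_that("protein distance matches the closed form and flags saturation", {
  p <- prepare_pair("ATGATG", "ATGATG")
  expect_equal(protein_distance(p)$d_prot, 0)

  # 2 of 4 residues differ: M A M A vs M K M K
  p <- prepare_pair("ATGGCTATGGCT", "ATGAAAATGAAA")
  pd <- protein_distance(p)
  expect_equal(pd$p_dist, 0.5)
  expect_equal(pd$d_prot, -log(0.5))
  expect_equal(protein_distance(p, "none")$d_prot, 0.5)

  p <- prepare_pair("ATG", "AAA")            # all residues differ
  pd <- protein_distance(p)
  expect_true(pd$saturated)
  expect_true(is.na(pd$d_prot))
})

test_that("dN/dS counting handles identity and purely synonymous change", {
  p <- prepare_pair("ATGGCT", "ATGGCT")
  nd <- estimate_dn_ds(p)
  expect_equal(nd$dN, 0)
  expect_equal(nd$dS, 0)
  expect_false(nd$omega_defined)

  # one synonymous difference in a 6-codon context: dN = 0, dS > 0, omega 0
  a <- "ATGGCTCTGACTCCAATT"
  b <- sub("GCT", "GCC", a)                  # Ala GCT -> Ala GCC
  nd <- estimate_dn_ds(prepare_pair(a, b))
  expect_equal(nd$dN, 0)
  expect_gt(nd$dS, 0)
  expect_equal(nd$omega, 0)
})

test_that("dN/dS and dR/dC match the enumeration oracle exactly on random pairs", {
  set.seed(421)
  for (rep in 1:200) {
    n <- sample(1:10, 1)
    sa <- random_codon_seq(n)
    sb <- random_codon_seq(n)
    p <- make_pair(sa, sb)
    o <- oracle_divergence(p$codons_a, p$codons_b)
    nd <- estimate_dn_ds(p)
    rc <- estimate_dr_dc(p)
    expect_scalar_equal(nd$S_sites, o$S_sites)
    expect_scalar_equal(nd$N_sites, o$N_sites)
    expect_scalar_equal(nd$Sd, o$Sd)
    expect_scalar_equal(nd$Nd, o$Nd)
    expect_scalar_equal(nd$dN, o$dN)
    expect_scalar_equal(nd$dS, o$dS)
    expect_scalar_equal(rc$N_R, o$N_R)
    expect_scalar_equal(rc$N_C, o$N_C)
    expect_scalar_equal(rc$O_R, o$O_R)
    expect_scalar_equal(rc$O_C, o$O_C)
    expect_scalar_equal(rc$dR, o$dR)
    expect_scalar_equal(rc$dC, o$dC)
  }
})

test_that("Dayhoff classification and dR/dC observed counts follow the classes", {
  expect_equal(classify_substitution("A", "G"), "conservative")
  expect_equal(classify_substitution("A", "D"), "radical")
  expect_error(classify_substitution("A", "X"), "not covered")
  expect_error(dayhoff_partition(c("AG", "GA")), "disjoint")
  expect_error(dayhoff_partition(c("AGPST", "DENQ")), "20 standard")

  p <- prepare_pair("GCAGGG", "GAAGGG")      # Ala->Glu at codon 1: radical
  rc <- estimate_dr_dc(p)
  expect_equal(rc$O_R, 1)
  expect_equal(rc$O_C, 0)

  p <- prepare_pair("GCAGGG", "GCAGGG")
  rc <- estimate_dr_dc(p)
  expect_equal(rc$dR, 0)
  expect_equal(rc$dC, 0)
  expect_false(rc$dRdC_defined)
})

test_that("divergence statistics are symmetric and conserve site/difference totals", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    sa <- random_codon_seq(n)
    sb <- random_codon_seq(n)
    p_ab <- make_pair(sa, sb)
    p_ba <- make_pair(sb, sa)
    nd_ab <- estimate_dn_ds(p_ab); nd_ba <- estimate_dn_ds(p_ba)
    rc_ab <- estimate_dr_dc(p_ab); rc_ba <- estimate_dr_dc(p_ba)
    expect_scalar_equal(nd_ab$dN, nd_ba$dN)
    expect_scalar_equal(nd_ab$dS, nd_ba$dS)
    expect_scalar_equal(rc_ab$dR, rc_ba$dR)
    expect_scalar_equal(rc_ab$dC, rc_ba$dC)
    expect_scalar_equal(protein_distance(p_ab)$p_dist,
                        protein_distance(p_ba)$p_dist)
    # conservation identities
    expect_equal(rc_ab$N_R + rc_ab$N_C, nd_ab$N_sites, tolerance = 1e-9)
    expect_equal(rc_ab$O_R + rc_ab$O_C, nd_ab$Nd, tolerance = 1e-9)
    # identity on self-pairs
    self <- estimate_dn_ds(make_pair(sa, sa))
    expect_equal(self$Nd + self$Sd, 0)
  }
})

test_that("region and charged-residue profiling anchors to reference coordinates", {
  # 10-residue protein, TM at 4-9, single E->D at position 5
  aa_to_codon <- c(M = "ATG", E = "GAA", D = "GAT", A = "GCT", N = "AAT",
                   K = "AAA", L = "CTT")
  mk <- function(res) paste(aa_to_codon[strsplit(res, "")[[1]]], collapse = "")
  sa <- mk("MAALEAAALA")
  sb <- mk("MAALDAAALA")
  regions <- c(rep("outside", 3), rep("TM", 6), "inside")
  p <- prepare_pair(sa, sb)
  prof <- region_and_charge_profile(p, regions)
  expect_equal(prof$n_diffs, 1)
  tm <- prof$region_tallies[prof$region_tallies$region == "TM", ]
  expect_equal(tm$conservative, 1)           # E and D share class DENQ
  expect_equal(tm$radical, 0)
  expect_equal(prof$charged_subs_total, 1)
  expect_equal(prof$charged_subs_in_TM, 1)

  # N -> K counts toward the charged set wherever it falls
  prof <- region_and_charge_profile(prepare_pair(mk("MAN"), mk("MAK")),
                                    rep("outside", 3))
  expect_equal(prof$charged_subs_total, 1)
  expect_equal(prof$charged_subs_in_TM, 0)
  tm0 <- prof$region_tallies[prof$region_tallies$region == "TM", ]
  expect_equal(tm0$radical + tm0$conservative, 0)

  expect_error(region_and_charge_profile(p, rep("TM", 3)), "length")
})

test_that("gapped reference coordinates still map region labels correctly", {
  # reference has a gap codon: annotation indexes its ungapped protein
  p <- prepare_pair("ATG---GAAGCT", "ATGAAAGAAGCT")
  expect_equal(p$ungapped_len_a, 3)
  expect_equal(p$pos_a, 1:3)
  prof <- region_and_charge_profile(p, c("outside", "TM", "inside"))
  expect_equal(sum(prof$region_tallies$radical +
                     prof$region_tallies$conservative), 0)
})

test_that("divergence_table flattens pairs with and without annotations", {
  pairs <- list(prepare_pair("ATGGCT", "ATGGAA", gene_id_a = "g1"),
                prepare_pair("ATGAAA", "ATGAAA", gene_id_a = "g2"))
  tab <- divergence_table(pairs)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("omega", "dRdC", "p_dist") %in% names(tab)))
  regs <- list(g1 = c("TM", "TM"), g2 = c("outside", "outside"))
  tab <- divergence_table(pairs, regions_by_gene = regs)
  expect_equal(tab$charged_subs_total, c(1, 0))  # Ala->Glu touches E
})
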