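toy_matrix <- function() {
  matrix(c(120, 40, 0,
           99, 80, 10,
           150, 0, 130),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("OrA", "OrB", "OrC"), c("o1", "o2", "o3")))
}

test_that("matrix filtering drops weak receptors then re-evaluates odorants", {
  fm <- filter_matrix(toy_matrix())
  # OrB (max 99) is dropped; o2's max over survivors is 40 -> dropped
  expect_setequal(rownames(fm), c("OrA", "OrC"))
  expect_setequal(colnames(fm), c("o1", "o3"))
  log <- attr(fm, "drop_log")
  expect_equal(log$dropped_receptors, "OrB")
  expect_equal(log$dropped_odorants, "o2")

  # boundary: a maximum of exactly 100 is retained
  m <- matrix(c(100, 99), 2, 1, dimnames = list(c("r1", "r2"), "o"))
  fm <- filter_matrix(m)
  expect_equal(rownames(fm), "r1")

  m0 <- matrix(0, 2, 2, dimnames = list(c("r1", "r2"), c("o1", "o2")))
  fm0 <- filter_matrix(m0)
  expect_equal(dim(fm0), c(0L, 0L))
  expect_length(attr(fm0, "drop_log")$dropped_receptors, 2)

  # idempotence
  fm2 <- filter_matrix(filter_matrix(toy_matrix()))
  expect_equal(unclass(fm2)[, ], unclass(filter_matrix(toy_matrix()))[, ])
  expect_error(filter_matrix(toy_matrix(), threshold = -1), "non-negative")
})

test_that("receptivity is the RPKM-weighted sum with negative responses clamped", {
  m <- matrix(c(50, 100), 2, 1, dimnames = list(c("r1", "r2"), "oX"))
  expect_equal(as.numeric(compute_receptivity(m, c(r1 = 10, r2 = 0))), 500)
  expect_equal(as.numeric(compute_receptivity(m, c(r1 = 5, r2 = 5))), 750)

  m_neg <- m; m_neg["r1", 1] <- -20
  expect_equal(as.numeric(compute_receptivity(m_neg, c(r1 = 10, r2 = 5))), 500)
  # clamping: any more-negative value changes nothing
  m_neg2 <- m; m_neg2["r1", 1] <- -2000
  expect_equal(compute_receptivity(m_neg2, c(r1 = 10, r2 = 5)),
               compute_receptivity(m_neg, c(r1 = 10, r2 = 5)))

  expect_error(compute_receptivity(m, c(r1 = 10)), "no RPKM")
  expect_error(compute_receptivity(m, c(r1 = -1, r2 = 0)), "non-negative")
})

test_that("receptivity change bands and sorts odorants by signed percent", {
  m <- matrix(c(50, 100), 2, 1, dimnames = list(c("r1", "r2"), "oX"))
  ag <- compute_receptivity(m, c(r1 = 10, r2 = 0), "gambiae")
  aq <- compute_receptivity(m, c(r1 = 5, r2 = 5), "quad")
  ch <- receptivity_change(ag, aq)
  expect_equal(ch$ratio, 2 / 3, tolerance = 1e-12)
  expect_equal(ch$signed_percent, -50)
  expect_equal(ch$band, "quad_enriched")

  # identical profiles: everything within the band
  ch <- receptivity_change(ag, ag)
  expect_equal(ch$signed_percent, 0)
  expect_equal(ch$band, "within_10pct")

  # the 10% boundary
  prof <- function(x) setNames(x, paste0("o", seq_along(x)))
  ch <- receptivity_change(prof(c(105, 125)), prof(c(100, 100)))
  expect_equal(ch$band[ch$odorant == "o1"], "within_10pct")
  expect_equal(ch$band[ch$odorant == "o2"], "gambiae_enriched")

  # both zero: flagged undefined and pushed to the end
  ch <- receptivity_change(prof(c(0, 200)), prof(c(0, 100)))
  expect_false(ch$defined[2])
  expect_equal(ch$odorant[1], "o2")
  # zero in one species only: one-sided enrichment
  ch <- receptivity_change(prof(c(0, 10)), prof(c(5, 10)))
  expect_equal(ch$band[ch$odorant == "o1"], "quad_enriched")
})

test_that("scaling one species' abundances scales ratios linearly", {
  sim <- simulate_response_matrix(seed = 3)
  fm <- filter_matrix(sim$matrix)
  pg <- compute_receptivity(fm, sim$rpkm_g)
  pq <- compute_receptivity(fm, sim$rpkm_q)
  pg3 <- compute_receptivity(fm, sim$rpkm_g * 3)
  expect_equal(as.numeric(pg3), 3 * as.numeric(pg))
  ch <- receptivity_change(pg, pq)
  ch3 <- receptivity_change(pg3, pq)
  idx <- match(ch$odorant, ch3$odorant)
  expect_equal(ch3$ratio[idx], 3 * ch$ratio, tolerance = 1e-12)

  # identical weights across species: everything within the band
  ch0 <- receptivity_change(pg, compute_receptivity(fm, sim$rpkm_g))
  expect_true(all(ch0$band[ch0$defined] == "within_10pct"))
})

test_that("the Fisher exact test matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(3, 3, 3, 3), 2))$p_value, 1)

  set.seed(17)
  for (rep in 1:150) {
    tab <- matrix(rmultinom(1, sample(5:40, 1), runif(4, 0.05, 1)), 2)
    mine <- fisher_exact_2x2(tab)$p_value
    expect_equal(mine, oracle_fisher_p(tab[1, 1], tab[1, 2],
                                       tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    expect_equal(mine, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 2), 2)), "non-negative")
})

test_that("class enrichment builds the right tables and flags empty strata", {
  changes <- data.frame(
    odorant = paste0("o", 1:8),
    receptivity_g = 1, receptivity_q = 1, ratio = 1,
    signed_percent = c(50, 60, 70, 80, -40, -55, -62, 5),
    band = c(rep("gambiae_enriched", 4), rep("quad_enriched", 3),
             "within_10pct"),
    defined = TRUE, stringsAsFactors = FALSE
  )
  meta <- data.frame(
    odorant = paste0("o", 1:8),
    class = c("ester", "ester", "ester", "ester",
              "alcohol", "alcohol", "alcohol", "ketone"),
    human_associated = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  enr <- class_enrichment(changes, meta, "chemical_class")
  ester <- enr[enr$group == "ester", ]
  # 4 esters all gambiae vs 3 non-esters all quad: the [[4,0],[0,3]] table
  expect_equal(c(ester$in_gambiae, ester$in_quad,
                 ester$out_gambiae, ester$out_quad), c(4, 0, 0, 3))
  expect_equal(ester$p_value, fisher_exact_2x2(matrix(c(4, 0, 0, 3), 2))$p_value)
  # ketone only appears within the band: empty stratum, not tested
  expect_false(enr$tested[enr$group == "ketone"])

  enr_h <- class_enrichment(changes, meta, "human_associated")
  expect_equal(nrow(enr_h), 1)
  expect_equal(enr_h$in_gambiae + enr_h$in_quad, 3)

  # restricting to larger changes drops odorants from the tables
  enr2 <- class_enrichment(changes, meta, "chemical_class",
                           min_abs_percent = 55)
  ester2 <- enr2[enr2$group == "ester", ]
  expect_equal(ester2$in_gambiae, 3)

  expect_error(class_enrichment(changes, meta[-1, ], "chemical_class"),
               "no metadata")
})
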