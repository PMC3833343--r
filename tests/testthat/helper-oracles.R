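# Independent oracles used to pin down expected values. These deliberately
# re-derive everything from first principles with their own code paths:
# explicit mutation loops for site counting, recursive depth-first pathway
# enumeration for difference counting, and choose()-arithmetic for the
# hypergeometric tail.

ORACLE_GC <- Biostrings::GENETIC_CODE
ORACLE_SENSE <- names(ORACLE_GC)[ORACLE_GC != "*"]
ORACLE_CLASSES <- c("AGPST", "DENQ", "HKR", "ILMV", "FWY", "C")

oracle_class_of <- local({
  res <- unlist(strsplit(ORACLE_CLASSES, ""))
  setNames(rep(seq_along(ORACLE_CLASSES), nchar(ORACLE_CLASSES)), res)
})

oracle_is_radical <- function(aa1, aa2) {
  oracle_class_of[[aa1]] != oracle_class_of[[aa2]]
}

# site fractions of one codon: loop over the 9 possible point mutations
oracle_codon_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  s <- n <- nr <- nc <- 0
  aa <- ORACLE_GC[[codon]]
  for (p in 1:3) {
    for (nt in nts) {
      if (nt == substr(codon, p, p)) next
      mut <- codon
      substr(mut, p, p) <- nt
      aa2 <- ORACLE_GC[[mut]]
      if (aa2 == "*") next
      if (aa2 == aa) s <- s + 1 / 3
      else {
        n <- n + 1 / 3
        if (oracle_is_radical(aa, aa2)) nr <- nr + 1 / 3 else nc <- nc + 1 / 3
      }
    }
  }
  c(S = s, N = n, N_R = nr, N_C = nc)
}

# difference counts of one codon pair, averaging over stop-free minimal
# pathways found by depth-first search over orderings
oracle_codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(Sd = 0, Nd = 0, O_R = 0, O_C = 0))
  acc <- list()
  walk <- function(cur, remaining, counts) {
    if (length(remaining) == 0) {
      acc[[length(acc) + 1]] <<- counts
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (ORACLE_GC[[nxt]] == "*") next
      aa1 <- ORACLE_GC[[cur]]; aa2 <- ORACLE_GC[[nxt]]
      step <- counts
      if (aa1 == aa2) step["Sd"] <- step["Sd"] + 1
      else {
        step["Nd"] <- step["Nd"] + 1
        if (oracle_is_radical(aa1, aa2)) step["O_R"] <- step["O_R"] + 1
        else step["O_C"] <- step["O_C"] + 1
      }
      walk(nxt, setdiff(remaining, p), step)
    }
    invisible()
  }
  walk(c1, pos, c(Sd = 0, Nd = 0, O_R = 0, O_C = 0))
  if (length(acc) == 0) return(NULL)       # every pathway hits a stop
  Reduce(`+`, acc) / length(acc)
}

oracle_jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)

# full NG86 + radical/conservative oracle over two codon vectors
oracle_divergence <- function(codons_a, codons_b) {
  sa <- rowSums(vapply(codons_a, oracle_codon_sites, numeric(4)))
  sb <- rowSums(vapply(codons_b, oracle_codon_sites, numeric(4)))
  sites <- (sa + sb) / 2
  diffs <- c(Sd = 0, Nd = 0, O_R = 0, O_C = 0)
  for (i in seq_along(codons_a)) {
    d <- oracle_codon_diffs(codons_a[i], codons_b[i])
    if (is.null(d)) stop("oracle: all pathways blocked for ",
                         codons_a[i], "/", codons_b[i])
    diffs <- diffs + d
  }
  pS <- if (sites["S"] > 0) diffs["Sd"] / sites["S"] else 0
  pN <- if (sites["N"] > 0) diffs["Nd"] / sites["N"] else 0
  pR <- if (sites["N_R"] > 0) diffs["O_R"] / sites["N_R"] else 0
  pC <- if (sites["N_C"] > 0) diffs["O_C"] / sites["N_C"] else 0
  list(S_sites = unname(sites["S"]), N_sites = unname(sites["N"]),
       N_R = unname(sites["N_R"]), N_C = unname(sites["N_C"]),
       Sd = unname(diffs["Sd"]), Nd = unname(diffs["Nd"]),
       O_R = unname(diffs["O_R"]), O_C = unname(diffs["O_C"]),
       dS = oracle_jc(unname(pS)), dN = oracle_jc(unname(pN)),
       dR = oracle_jc(unname(pR)), dC = oracle_jc(unname(pC)))
}

# two-sided Fisher p for a 2x2 table by direct choose() arithmetic
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(N, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(N, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

random_codon_seq <- function(n) paste(sample(ORACLE_SENSE, n, replace = TRUE),
                                      collapse = "")

make_pair <- function(sa, sb) prepare_pair(sa, sb)

expect_scalar_equal <- function(x, y, tol = 1e-12) {
  if (is.na(x) || is.na(y)) expect_true(is.na(x) && is.na(y))
  else expect_equal(x, y, tolerance = tol)
}
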