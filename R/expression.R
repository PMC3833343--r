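# Abundance quantification (RPKM), single-replicate "reliable" log2 fold
# change via a Poisson-Gamma posterior, Spearman rank-order conservation,
# and dN/dS-quartile contrasts of transcript enrichment.

#' RPKM normalization of a two-sample count table
#'
#' RPKM = 1e9 * count / (library_size * gene_length). A gene is flagged
#' detectable in a sample when its count is positive and, optionally, its
#' RPKM reaches `min_rpkm`.
#'
#' @param counts data frame with columns `gene_id`, `count_a`, `count_b`,
#'   `length`
#' @param lib_a,lib_b total mapped reads per sample (must be positive)
#' @param min_rpkm optional RPKM detectability threshold (default: any
#'   positive count is detectable)
#' @return the input with added columns `rpkm_a`, `rpkm_b`, `detectable_a`,
#'   `detectable_b`
#' @export
compute_rpkm <- function(counts, lib_a, lib_b, min_rpkm = 0) {
  need <- c("gene_id", "count_a", "count_b", "length")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "))
  }
  if (lib_a <= 0 || lib_b <= 0) stop("library sizes must be positive")
  if (any(counts$length <= 0)) stop("gene lengths must be positive")
  if (any(counts$count_a < 0) || any(counts$count_b < 0)) {
    stop("counts must be non-negative")
  }
  counts$rpkm_a <- 1e9 * counts$count_a / (lib_a * counts$length)
  counts$rpkm_b <- 1e9 * counts$count_b / (lib_b * counts$length)
  counts$detectable_a <- counts$count_a > 0 & counts$rpkm_a >= min_rpkm
  counts$detectable_b <- counts$count_b > 0 & counts$rpkm_b >= min_rpkm
  counts
}

#' Reliable log2 fold change for single-replicate counts
#'
#' A conservative posterior bound on the log2 fold change between two
#' single-replicate samples. Each expression rate gets an independent
#' Gamma(count + 1) posterior (Poisson likelihood, flat prior) scaled by its
#' library size; the posterior of z = log2(rate_b / rate_a) is sampled by
#' Monte Carlo, and with q_lo and q_hi the (1 - c) and c quantiles of z the
#' reliable fold change is q_lo when q_lo > 0, q_hi when q_hi < 0, and 0
#' otherwise. A value of 0 means "not significantly different"; any other
#' value is a credible bound whose magnitude never exceeds the raw ratio
#' (shrinkage). Deterministic given `seed`.
#'
#' @param count_a,count_b integer read counts (vectors of equal length)
#' @param lib_a,lib_b library sizes (scalars or vectors)
#' @param c credibility level in (0.5, 1); default 0.99
#' @param draws Monte-Carlo draws per gene (default 1e5)
#' @param seed integer seed
#' @return data frame with `raw_log2fc` (NA when either count is 0), `gfold`
#'   and `significant` (gfold != 0)
#' @examples
#' reliable_log2_fold(1000, 125, 1e6, 1e6, seed = 1)
#' @export
reliable_log2_fold <- function(count_a, count_b, lib_a, lib_b,
                               c = 0.99, draws = 1e5, seed = 1) {
  if (c <= 0.5 || c >= 1) stop("credibility level c must be in (0.5, 1)")
  if (any(count_a < 0) || any(count_b < 0)) stop("counts must be non-negative")
  if (any(count_a != round(count_a)) || any(count_b != round(count_b))) {
    stop("counts must be integers")
  }
  n <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, n); count_b <- rep_len(count_b, n)
  lib_a <- rep_len(lib_a, n); lib_b <- rep_len(lib_b, n)
  if (any(lib_a <= 0) || any(lib_b <= 0)) stop("library sizes must be positive")
  gfold <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      ra <- rgamma(draws, shape = count_a[i] + 1) / lib_a[i]
      rb <- rgamma(draws, shape = count_b[i] + 1) / lib_b[i]
      z <- log2(rb) - log2(ra)
      q <- quantile(z, c(1 - c, c), names = FALSE)
      gfold[i] <- if (q[1] > 0) q[1] else if (q[2] < 0) q[2] else 0
    }
  })
  raw <- ifelse(count_a > 0 & count_b > 0,
                log2((count_b / lib_b) / (count_a / lib_a)), NA_real_)
  data.frame(raw_log2fc = raw, gfold = gfold, significant = gfold != 0)
}

#' Fold-change table for a two-sample count table
#'
#' @inheritParams compute_rpkm
#' @inheritParams reliable_log2_fold
#' @return the RPKM table with `raw_log2fc`, `gfold`, `significant` appended
#' @export
fold_change_table <- function(counts, lib_a, lib_b, c = 0.99,
                              draws = 1e5, seed = 1, min_rpkm = 0) {
  ab <- compute_rpkm(counts, lib_a, lib_b, min_rpkm = min_rpkm)
  fc <- reliable_log2_fold(counts$count_a, counts$count_b, lib_a, lib_b,
                           c = c, draws = draws, seed = seed)
  cbind(ab, fc)
}

#' Spearman rank-order conservation of a gene family's abundances
#'
#' Rank correlation of the two species' abundances over a gene subset,
#' restricted to genes detectable in both species; ties are mid-ranked.
#'
#' @param abund an RPKM table from [compute_rpkm()]
#' @param gene_subset gene ids of the family to correlate (default: all)
#' @return Spearman's rho
#' @export
rank_correlation <- function(abund, gene_subset = abund$gene_id) {
  sub <- abund[abund$gene_id %in% gene_subset &
                 abund$detectable_a & abund$detectable_b, ]
  if (nrow(sub) < 3) {
    stop("need at least 3 genes detectable in both species, have ", nrow(sub))
  }
  cor(sub$rpkm_a, sub$rpkm_b, method = "spearman")
}

#' Transcript-enrichment contrast across dN/dS quartiles
#'
#' Splits genes into quartiles of their dN/dS ratio, summarizes the absolute
#' reliable fold change |gfold| per quartile (median and variance), and
#' tests the first (most conserved) quartile against the upper three pooled,
#' plus each upper quartile individually, with two-sided Wilcoxon rank-sum
#' tests.
#'
#' @param omega_by_gene named numeric vector of dN/dS per gene
#' @param gfold_by_gene named numeric vector of reliable log2 fold changes
#' @return list with `quartiles` (per-gene assignment), `summary` (per-
#'   quartile n, median, variance of |gfold|), `q1_vs_rest` (htest),
#'   `pairwise` (data frame of Q1-vs-Qk tests) and `degenerate` flag
#' @export
quartile_contrast <- function(omega_by_gene, gfold_by_gene) {
  genes <- intersect(names(omega_by_gene), names(gfold_by_gene))
  if (length(genes) < 8) stop("need at least 8 shared genes, have ", length(genes))
  omega <- omega_by_gene[genes]
  g <- abs(gfold_by_gene[genes])
  if (length(unique(omega)) == 1) {
    return(list(degenerate = TRUE, quartiles = NULL, summary = NULL,
                q1_vs_rest = NULL, pairwise = NULL))
  }
  br <- unique(quantile(omega, probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE))
  q <- cut(omega, breaks = br, include.lowest = TRUE,
           labels = paste0("Q", seq_len(length(br) - 1)))
  summ <- do.call(rbind, lapply(levels(q), function(l) {
    data.frame(quartile = l, n = sum(q == l),
               median_abs_gfold = median(g[q == l]),
               var_abs_gfold = if (sum(q == l) > 1) var(g[q == l]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  q1 <- levels(q)[1]
  test_main <- wilcox.test(g[q == q1], g[q != q1], exact = FALSE)
  pw <- do.call(rbind, lapply(levels(q)[-1], function(l) {
    ht <- wilcox.test(g[q == q1], g[q == l], exact = FALSE)
    data.frame(comparison = paste0(q1, "_vs_", l),
               W = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  }))
  list(degenerate = FALSE,
       quartiles = setNames(as.character(q), genes),
       summary = summ, q1_vs_rest = test_main, pairwise = pw)
}
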