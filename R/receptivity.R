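# The antennal odorant-receptivity model: an odorant-receptor deorphanization
# response matrix (receptor x odorant, delta spikes/s over baseline) is
# filtered for robust responders, weighted by each species' receptor RPKMs,
# and summed per odorant into an "antennal receptivity"; the interspecific
# ratio is banded and chemical classes are tested for disproportionate
# representation with a two-sided Fisher exact test.

#' Filter a response matrix for robust receptors and odorants
#'
#' Drops every receptor whose maximum response is below `threshold`, then
#' every odorant whose maximum response over the surviving receptors is
#' below `threshold` (receptors first, then odorants; the order is fixed).
#' Missing cells (NA) are ignored when maxima are taken.
#'
#' @param m numeric matrix, receptors in rows, odorants in columns; NA marks
#'   an unassayed cell
#' @param threshold minimum delta spikes/s a receptor or odorant must reach
#'   in at least one assay (default 100, inclusive)
#' @return the filtered matrix, with a `drop_log` attribute listing dropped
#'   receptor and odorant names
#' @export
filter_matrix <- function(m, threshold = 100) {
  if (threshold < 0) stop("threshold must be non-negative")
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0) {
    stop("response matrix must be a non-empty matrix")
  }
  row_max <- apply(m, 1, function(x) if (all(is.na(x))) -Inf else max(x, na.rm = TRUE))
  keep_r <- row_max >= threshold
  m2 <- m[keep_r, , drop = FALSE]
  if (nrow(m2) > 0) {
    col_max <- apply(m2, 2, function(x) if (all(is.na(x))) -Inf else max(x, na.rm = TRUE))
    keep_o <- col_max >= threshold
  } else {
    keep_o <- rep(FALSE, ncol(m))
  }
  out <- m2[, keep_o, drop = FALSE]
  attr(out, "drop_log") <- list(
    dropped_receptors = rownames(m)[!keep_r],
    dropped_odorants = colnames(m)[!keep_o]
  )
  out
}

#' Antennal receptivity profile for one species
#'
#' Weights each receptor's response to each odorant by that receptor's
#' normalized abundance (RPKM) in the species and sums over receptors:
#' A(o) = sum_r RPKM(r) * max(response(r, o), 0). Odor-induced decreases in
#' spiking (negative responses) are indeterminate and contribute exactly 0;
#' missing cells are treated as 0 and counted.
#'
#' @param m response matrix (receptors x odorants), typically filtered with
#'   [filter_matrix()]
#' @param rpkm named vector of per-receptor abundances; every receptor of
#'   `m` must be present and non-negative
#' @param species label attached to the profile
#' @return named numeric vector of per-odorant receptivities with
#'   attributes `species` and `n_imputed` (missing cells treated as 0)
#' @examples
#' m <- matrix(c(50, 100), 2, 1, dimnames = list(c("r1", "r2"), "odorX"))
#' compute_receptivity(m, c(r1 = 10, r2 = 0))  # 500
#' @export
compute_receptivity <- function(m, rpkm, species = "species") {
  if (is.null(rownames(m))) stop("response matrix needs receptor rownames")
  missing_r <- setdiff(rownames(m), names(rpkm))
  if (length(missing_r)) {
    stop("no RPKM for receptor(s): ", paste(missing_r, collapse = ", "))
  }
  w <- rpkm[rownames(m)]
  if (any(w < 0)) stop("RPKM weights must be non-negative")
  n_imputed <- sum(is.na(m))
  resp <- pmax(m, 0)
  resp[is.na(resp)] <- 0
  a <- as.numeric(crossprod(resp, w))
  names(a) <- colnames(m)
  attr(a, "species") <- species
  attr(a, "n_imputed") <- n_imputed
  a
}

#' Interspecific receptivity change per odorant
#'
#' Divides the first species' antennal receptivity by the second's per
#' odorant, converts the ratio to a symmetric signed percent
#' (100 * (rho - 1) for rho >= 1, -100 * (1/rho - 1) otherwise), and bands
#' each odorant: `within_10pct` when the absolute signed percent is at most
#' `band`, otherwise enriched in whichever species has the larger
#' receptivity. Odorants with zero receptivity in both species are flagged
#' undefined and excluded from the sorted output order; zero in only one
#' species gives an infinite signed percent, reported as one-sided
#' enrichment.
#'
#' @param profile_g,profile_q per-odorant receptivity vectors from
#'   [compute_receptivity()], over the same odorants
#' @param band percent half-width of the "no change" band (default 10)
#' @return data frame (odorant, receptivity_g, receptivity_q, ratio,
#'   signed_percent, band, defined), sorted by decreasing signed percent with
#'   undefined odorants last
#' @export
receptivity_change <- function(profile_g, profile_q, band = 10) {
  if (!setequal(names(profile_g), names(profile_q))) {
    stop("the two profiles must cover the same odorants")
  }
  profile_q <- profile_q[names(profile_g)]
  ag <- as.numeric(profile_g)
  aq <- as.numeric(profile_q)
  defined <- !(ag == 0 & aq == 0)
  rho <- ifelse(defined, ag / aq, NA_real_)
  signed <- ifelse(!defined, NA_real_,
                   ifelse(rho >= 1, 100 * (rho - 1), -100 * (1 / rho - 1)))
  band_lab <- ifelse(!defined, NA_character_,
                     ifelse(abs(signed) <= band, "within_10pct",
                            ifelse(signed > 0, "gambiae_enriched",
                                   "quad_enriched")))
  out <- data.frame(
    odorant = names(profile_g),
    receptivity_g = ag, receptivity_q = aq,
    ratio = rho, signed_percent = signed, band = band_lab,
    defined = defined,
    stringsAsFactors = FALSE
  )
  def <- out[out$defined, , drop = FALSE]
  def <- def[order(-def$signed_percent), , drop = FALSE]
  rbind(def, out[!out$defined, , drop = FALSE])
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration: with margins
#' fixed, the p-value is the sum of probabilities of all tables no more
#' probable than the observed one (within a relative tolerance of 1e-7, the
#' conventional guard against floating-point ties).
#'
#' @param tab 2x2 integer matrix
#' @return list with `p_value`, `odds_ratio` (sample odds ratio; Inf/NaN
#'   possible on zero margins) and the input table
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p_value  # 1/3
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    stop("need a 2x2 table of non-negative integers")
  }
  a <- tab[1, 1]
  m <- sum(tab[1, ])          # white balls: row 1
  n <- sum(tab[2, ])          # black balls: row 2
  k <- sum(tab[, 1])          # draws: column 1
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = min(p, 1), odds_ratio = or, table = tab)
}

#' Chemical-class enrichment of receptivity changes
#'
#' For each group (chemical class, or the human-associated flag), builds the
#' 2x2 table of (in-group vs out-group) x (gambiae-enriched vs
#' quad-enriched) over the odorants that changed band, optionally restricted
#' to changes larger than `min_abs_percent`, and applies the two-sided
#' Fisher exact test. Odorants in the no-change band or with undefined
#' change are excluded. Groups with no odorant among the tested set are
#' flagged and not tested.
#'
#' @param changes data frame from [receptivity_change()]
#' @param meta data frame with columns `odorant`, `class`,
#'   `human_associated`
#' @param grouping `"chemical_class"` (one test per class) or
#'   `"human_associated"` (one test)
#' @param min_abs_percent optional: only odorants with
#'   `abs(signed_percent) > min_abs_percent` enter the tables
#' @return data frame (group, in_gambiae, in_quad, out_gambiae, out_quad,
#'   odds_ratio, p_value, tested)
#' @export
class_enrichment <- function(changes, meta,
                             grouping = c("chemical_class", "human_associated"),
                             min_abs_percent = NULL) {
  grouping <- match.arg(grouping)
  missing_meta <- setdiff(changes$odorant, meta$odorant)
  if (length(missing_meta)) {
    stop("no metadata for odorant(s): ", paste(missing_meta, collapse = ", "))
  }
  d <- changes[changes$defined & changes$band != "within_10pct", , drop = FALSE]
  if (!is.null(min_abs_percent)) {
    d <- d[is.infinite(d$signed_percent) |
             abs(d$signed_percent) > min_abs_percent, , drop = FALSE]
  }
  idx <- match(d$odorant, meta$odorant)
  groups <- if (grouping == "chemical_class") {
    setNames(as.character(meta$class[idx]), d$odorant)
  } else {
    setNames(ifelse(meta$human_associated[idx], "human_associated",
                    "not_human_associated"), d$odorant)
  }
  gamb <- d$band == "gambiae_enriched"
  level_set <- if (grouping == "chemical_class") {
    unique(as.character(meta$class))
  } else {
    "human_associated"
  }
  rows <- lapply(level_set, function(g) {
    ing <- groups == g
    tab <- matrix(c(sum(ing & gamb), sum(!ing & gamb),
                    sum(ing & !gamb), sum(!ing & !gamb)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("gambiae", "quad"), c("in", "out")))
    tested <- sum(ing) > 0
    ft <- if (tested) fisher_exact_2x2(t(tab)) else NULL
    data.frame(
      group = g,
      in_gambiae = tab["gambiae", "in"], in_quad = tab["quad", "in"],
      out_gambiae = tab["gambiae", "out"], out_quad = tab["quad", "out"],
      odds_ratio = if (tested) ft$odds_ratio else NA_real_,
      p_value = if (tested) ft$p_value else NA_real_,
      tested = tested,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
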