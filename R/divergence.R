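# Pairwise molecular-evolution statistics on codon-aligned ortholog pairs:
# protein distance, NG86-style dN/dS, radical/conservative dR/dC under the
# Dayhoff classes, and region/charged-residue substitution profiling.

#' Validate and clean a codon-aligned ortholog pair
#'
#' Takes two aligned coding sequences (same aligned length, multiple of 3,
#' gaps as `-`), splits them into codon columns, and drops pairwise every
#' column that contains a gap in either sequence or a stop codon in either
#' sequence. The retained columns are the unit of all downstream divergence
#' statistics. Positions of retained columns in the ungapped protein of the
#' first (reference) sequence are recorded so that membrane-topology
#' annotations can be applied later.
#'
#' @param seq_a,seq_b aligned CDS strings (or length-1 `DNAStringSet` /
#'   `character`); `seq_a` is the reference sequence for region profiling
#' @param gene_id_a,gene_id_b,species_a,species_b identifiers carried through
#'   to output tables
#' @return an object of class `codon_pair` with fields `codons_a`, `codons_b`
#'   (retained codon columns), `n_codons`, `pos_a` (reference ungapped codon
#'   index of each retained column), `ungapped_len_a`, and `dropped`
#'   (a data frame reporting every removed column and the reason)
#' @examples
#' p <- prepare_pair("ATG---AAA", "ATGCCCAAA")
#' p$n_codons  # 2: the gap column is dropped
#' @export
prepare_pair <- function(seq_a, seq_b,
                         gene_id_a = "gene_a", gene_id_b = "gene_b",
                         species_a = "species_a", species_b = "species_b") {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (length(seq_a) != 1 || length(seq_b) != 1) {
    stop("prepare_pair expects single sequences")
  }
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length (", nchar(seq_a),
         " vs ", nchar(seq_b), ")")
  }
  if (nchar(seq_a) %% 3 != 0) {
    stop("aligned length must be a multiple of 3, got ", nchar(seq_a))
  }
  if (grepl("[^ACGT-]", seq_a) || grepl("[^ACGT-]", seq_b)) {
    stop("sequences may only contain A, C, G, T and '-'")
  }
  n_col <- nchar(seq_a) / 3
  split_codons <- function(s) {
    substring(s, 3 * seq_len(n_col) - 2, 3 * seq_len(n_col))
  }
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  gc <- .genetic_code()
  gap <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
  aa_a <- ifelse(gap, NA_character_, unname(gc[ca]))
  aa_b <- ifelse(gap, NA_character_, unname(gc[cb]))
  stop_col <- !gap & (aa_a == "*" | aa_b == "*")
  keep <- !gap & !stop_col
  # reference ungapped codon index: counts sense, non-gap codons of seq_a
  counts_a <- !grepl("-", ca, fixed = TRUE) & !is.na(match(ca, names(gc))) &
    unname(gc[ca]) != "*"
  counts_a[is.na(counts_a)] <- FALSE
  pos_all <- cumsum(counts_a)
  dropped <- data.frame(
    column = which(!keep),
    codon_a = ca[!keep],
    codon_b = cb[!keep],
    reason = ifelse(gap[!keep], "gap", "stop"),
    stringsAsFactors = FALSE
  )
  structure(list(
    gene_id_a = gene_id_a, gene_id_b = gene_id_b,
    species_a = species_a, species_b = species_b,
    codons_a = ca[keep], codons_b = cb[keep],
    n_codons = sum(keep),
    pos_a = pos_all[keep],
    ungapped_len_a = sum(counts_a),
    dropped = dropped
  ), class = "codon_pair")
}

#' @export
print.codon_pair <- function(x, ...) {
  cat("codon_pair: ", x$gene_id_a, " (", x$species_a, ") vs ",
      x$gene_id_b, " (", x$species_b, ")\n", sep = "")
  cat("  retained codons:", x$n_codons,
      " dropped columns:", nrow(x$dropped), "\n")
  invisible(x)
}

.pair_aa <- function(pair) {
  gc <- .genetic_code()
  list(a = unname(gc[pair$codons_a]), b = unname(gc[pair$codons_b]))
}

#' Protein distance between the two sequences of a pair
#'
#' The proportion of differing residues over retained codon columns
#' (p-distance), optionally Poisson-corrected as d = -ln(1 - p). Saturated
#' pairs (p >= 1) have an undefined corrected distance, flagged rather than
#' returned as infinity.
#'
#' @param pair a [prepare_pair()] result
#' @param correction `"poisson"` (default) or `"none"`
#' @return list with `p_dist`, `d_prot`, `correction`, `saturated`
#' @export
protein_distance <- function(pair, correction = c("poisson", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(pair, "codon_pair"))
  if (pair$n_codons == 0) stop("empty pair: no retained codon columns")
  aa <- .pair_aa(pair)
  p <- mean(aa$a != aa$b)
  saturated <- FALSE
  d <- p
  if (correction == "poisson") {
    if (p >= 1) {
      saturated <- TRUE
      d <- NA_real_
    } else {
      d <- -log(1 - p)
    }
  }
  list(p_dist = p, d_prot = d, correction = correction, saturated = saturated)
}

#' Pairwise dN/dS by codon counting
#'
#' Nei-Gojobori-style counting estimator: synonymous and nonsynonymous site
#' fractions are computed per codon (single-nucleotide changes to stop codons
#' disregarded) and averaged over the two sequences; observed differences in
#' codons differing at several positions are averaged over all minimal
#' mutational pathways, excluding pathways through stop codons; the resulting
#' proportions are Jukes-Cantor corrected, d = -3/4 ln(1 - 4p/3).
#'
#' omega = dN/dS is flagged undefined (NA) when dS = 0 or either rate is
#' saturated (p >= 3/4).
#'
#' @param pair a [prepare_pair()] result
#' @return list with `dN`, `dS`, `omega`, `N_sites`, `S_sites`, `Nd`, `Sd`,
#'   `pN`, `pS` and the logical flags `dN_defined`, `dS_defined`,
#'   `omega_defined`
#' @export
estimate_dn_ds <- function(pair) {
  stopifnot(inherits(pair, "codon_pair"))
  if (pair$n_codons == 0) stop("empty pair: no retained codon columns")
  sites <- .site_table()
  tabs <- .pair_tables()
  S_sites <- (sum(sites[pair$codons_a, "S"]) + sum(sites[pair$codons_b, "S"])) / 2
  N_sites <- (sum(sites[pair$codons_a, "N"]) + sum(sites[pair$codons_b, "N"])) / 2
  idx <- cbind(pair$codons_a, pair$codons_b)
  Sd <- sum(tabs$Sd[idx])
  Nd <- sum(tabs$Nd[idx])
  pS <- if (S_sites > 0) Sd / S_sites else 0
  pN <- if (N_sites > 0) Nd / N_sites else 0
  dS <- .jc_correct(pS)
  dN <- .jc_correct(pN)
  dS_defined <- !is.na(dS)
  dN_defined <- !is.na(dN)
  omega_defined <- dN_defined && dS_defined && dS > 0
  omega <- if (omega_defined) dN / dS else NA_real_
  list(dN = dN, dS = dS, omega = omega,
       N_sites = N_sites, S_sites = S_sites, Nd = Nd, Sd = Sd,
       pN = pN, pS = pS,
       dN_defined = dN_defined, dS_defined = dS_defined,
       omega_defined = omega_defined)
}

#' Radical vs conservative nonsynonymous rates (dR/dC)
#'
#' Partitions the nonsynonymous sites of each codon into radical and
#' conservative fractions according to a residue partition (each possible
#' single-nucleotide amino-acid change contributes 1/3 of a site to the class
#' of that change), classifies observed nonsynonymous differences with the
#' same pathway averaging as [estimate_dn_ds()], and Jukes-Cantor corrects
#' p_R = O_R/N_R and p_C = O_C/N_C. The ratio dR/dC is flagged undefined when
#' dC = 0 or either rate is saturated.
#'
#' @param pair a [prepare_pair()] result
#' @param partition a [dayhoff_partition()]
#' @return list with `dR`, `dC`, `dRdC`, `N_R`, `N_C`, `O_R`, `O_C`, `p_R`,
#'   `p_C` and definedness flags
#' @export
estimate_dr_dc <- function(pair, partition = dayhoff_partition()) {
  stopifnot(inherits(pair, "codon_pair"))
  if (pair$n_codons == 0) stop("empty pair: no retained codon columns")
  sites <- .site_table(partition)
  tabs <- .pair_tables(partition)
  N_R <- (sum(sites[pair$codons_a, "N_R"]) + sum(sites[pair$codons_b, "N_R"])) / 2
  N_C <- (sum(sites[pair$codons_a, "N_C"]) + sum(sites[pair$codons_b, "N_C"])) / 2
  idx <- cbind(pair$codons_a, pair$codons_b)
  O_R <- sum(tabs$O_R[idx])
  O_C <- sum(tabs$O_C[idx])
  p_R <- if (N_R > 0) O_R / N_R else 0
  p_C <- if (N_C > 0) O_C / N_C else 0
  dR <- .jc_correct(p_R)
  dC <- .jc_correct(p_C)
  dR_defined <- !is.na(dR)
  dC_defined <- !is.na(dC)
  ratio_defined <- dR_defined && dC_defined && dC > 0
  dRdC <- if (ratio_defined) dR / dC else NA_real_
  list(dR = dR, dC = dC, dRdC = dRdC,
       N_R = N_R, N_C = N_C, O_R = O_R, O_C = O_C,
       p_R = p_R, p_C = p_C,
       dR_defined = dR_defined, dC_defined = dC_defined,
       dRdC_defined = ratio_defined)
}

#' Region-stratified and charged-residue substitution profile
#'
#' Assigns every differing residue column of a pair to a membrane-topology
#' region (e.g. TM / inside / outside) through the reference sequence's
#' ungapped coordinates, tallies radical and conservative changes per region,
#' and counts substitutions touching a configurable residue set (default
#' E, N, Y) overall and within TM regions.
#'
#' @param pair a [prepare_pair()] result
#' @param regions character vector of per-residue region labels in ungapped
#'   coordinates of the reference (first) sequence; length must equal the
#'   reference's ungapped protein length
#' @param partition a [dayhoff_partition()] used to classify each change
#' @param charged_set residues whose replacement (in either direction) counts
#'   toward `charged_subs_total`
#' @param tm_label the region label treated as transmembrane
#' @return list with `region_tallies` (data frame: region, radical,
#'   conservative), `charged_subs_total`, `charged_subs_in_TM`, `n_diffs`,
#'   `n_unassigned`
#' @export
region_and_charge_profile <- function(pair, regions,
                                      partition = dayhoff_partition(),
                                      charged_set = c("E", "N", "Y"),
                                      tm_label = "TM") {
  stopifnot(inherits(pair, "codon_pair"))
  regions <- as.character(regions)
  if (length(regions) != pair$ungapped_len_a) {
    stop("region annotation length (", length(regions),
         ") does not match reference ungapped protein length (",
         pair$ungapped_len_a, ")")
  }
  aa <- .pair_aa(pair)
  diff <- which(aa$a != aa$b)
  levels_seen <- unique(c(tm_label, regions))
  tally <- matrix(0L, nrow = length(levels_seen), ncol = 2,
                  dimnames = list(levels_seen, c("radical", "conservative")))
  charged_total <- 0L
  charged_tm <- 0L
  unassigned <- 0L
  for (i in diff) {
    p <- pair$pos_a[i]
    if (is.na(p) || p < 1 || p > length(regions)) {
      unassigned <- unassigned + 1L
      next
    }
    reg <- regions[p]
    cls <- classify_substitution(aa$a[i], aa$b[i], partition)
    tally[reg, cls] <- tally[reg, cls] + 1L
    if (aa$a[i] %in% charged_set || aa$b[i] %in% charged_set) {
      charged_total <- charged_total + 1L
      if (reg == tm_label) charged_tm <- charged_tm + 1L
    }
  }
  list(
    region_tallies = data.frame(
      region = rownames(tally),
      radical = unname(tally[, "radical"]),
      conservative = unname(tally[, "conservative"]),
      stringsAsFactors = FALSE
    ),
    charged_subs_total = charged_total,
    charged_subs_in_TM = charged_tm,
    n_diffs = length(diff),
    n_unassigned = unassigned
  )
}

#' All divergence statistics for one pair as a single row
#'
#' Convenience wrapper running [protein_distance()], [estimate_dn_ds()],
#' [estimate_dr_dc()] and optionally [region_and_charge_profile()] and
#' flattening the results into a one-row data frame suitable for a per-pair
#' output table.
#'
#' @inheritParams region_and_charge_profile
#' @param regions optional per-residue region labels for the reference
#'   sequence; when `NULL` region profiling is skipped
#' @param correction protein-distance correction passed to
#'   [protein_distance()]
#' @return one-row data frame
#' @export
divergence_estimates <- function(pair, regions = NULL,
                                 partition = dayhoff_partition(),
                                 charged_set = c("E", "N", "Y"),
                                 correction = "poisson") {
  pd <- protein_distance(pair, correction)
  nd <- estimate_dn_ds(pair)
  rc <- estimate_dr_dc(pair, partition)
  row <- data.frame(
    gene_id_a = pair$gene_id_a, gene_id_b = pair$gene_id_b,
    species_a = pair$species_a, species_b = pair$species_b,
    n_codons = pair$n_codons,
    p_dist = pd$p_dist, d_prot = pd$d_prot,
    dN = nd$dN, dS = nd$dS, omega = nd$omega,
    N_sites = nd$N_sites, S_sites = nd$S_sites,
    Nd = nd$Nd, Sd = nd$Sd,
    dR = rc$dR, dC = rc$dC, dRdC = rc$dRdC,
    N_R = rc$N_R, N_C = rc$N_C, O_R = rc$O_R, O_C = rc$O_C,
    omega_defined = nd$omega_defined, dRdC_defined = rc$dRdC_defined,
    stringsAsFactors = FALSE
  )
  if (!is.null(regions)) {
    prof <- region_and_charge_profile(pair, regions, partition, charged_set)
    tm <- prof$region_tallies[prof$region_tallies$region == "TM", , drop = FALSE]
    row$tm_radical <- if (nrow(tm)) tm$radical else 0L
    row$tm_conservative <- if (nrow(tm)) tm$conservative else 0L
    row$charged_subs_total <- prof$charged_subs_total
    row$charged_subs_in_TM <- prof$charged_subs_in_TM
  }
  row
}

#' Divergence table for a list of pairs
#'
#' @param pairs list of [prepare_pair()] results
#' @param regions_by_gene optional named list of region label vectors keyed
#'   by reference gene id
#' @inheritParams divergence_estimates
#' @return data frame with one row per pair
#' @export
divergence_table <- function(pairs, regions_by_gene = NULL,
                             partition = dayhoff_partition(),
                             charged_set = c("E", "N", "Y")) {
  rows <- lapply(pairs, function(p) {
    reg <- if (!is.null(regions_by_gene)) regions_by_gene[[p$gene_id_a]] else NULL
    divergence_estimates(p, regions = reg, partition = partition,
                         charged_set = charged_set)
  })
  do.call(rbind, rows)
}

#' Read an aligned ortholog pair from a two-record FASTA file
#'
#' @param path FASTA file containing exactly two aligned CDS records; the
#'   first record is the reference sequence
#' @param species_a,species_b species labels for the two records
#' @return a [prepare_pair()] result
#' @export
read_pair_fasta <- function(path, species_a = "species_a",
                            species_b = "species_b") {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 2) {
    stop("expected exactly 2 records in ", path, ", found ", length(seqs))
  }
  prepare_pair(as.character(seqs[[1]]), as.character(seqs[[2]]),
               gene_id_a = names(seqs)[1], gene_id_b = names(seqs)[2],
               species_a = species_a, species_b = species_b)
}
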