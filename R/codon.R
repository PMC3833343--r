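# Codon-level machinery shared by the divergence estimators: the standard
# genetic code (from Biostrings), the Dayhoff residue partition, per-codon
# synonymous/nonsynonymous site fractions, and pathway-averaged difference
# counts for every codon pair. All tables are precomputed once and cached.

.genetic_code <- function() Biostrings::GENETIC_CODE

.all_codons <- function() names(.genetic_code())

.sense_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc != "*"]
}

.translate_codon <- function(codon) unname(.genetic_code()[codon])

#' Dayhoff physicochemical residue partition
#'
#' Builds the residue partition used to classify nonsynonymous substitutions
#' as conservative (within a class) or radical (between classes). The default
#' classes are the six Dayhoff groups AGPST, DENQ, HKR, ILMV, FWY and C.
#'
#' @param classes character vector of residue groups; groups must be disjoint
#'   and jointly cover the 20 standard amino acids
#' @return an object of class `dayhoff_partition` with a residue-to-class
#'   lookup and a `classify(aa1, aa2)` convention: same class = conservative,
#'   different class = radical
#' @examples
#' part <- dayhoff_partition()
#' classify_substitution("A", "G", part)  # conservative
#' classify_substitution("A", "D", part)  # radical
#' @export
dayhoff_partition <- function(classes = c("AGPST", "DENQ", "HKR", "ILMV", "FWY", "C")) {
  if (length(classes) == 0) stop("partition must contain at least one class")
  residues <- unlist(strsplit(classes, ""))
  if (anyDuplicated(residues)) stop("partition classes must be disjoint")
  std <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (!all(std %in% residues)) {
    stop("partition must cover the 20 standard residues; missing: ",
         paste(setdiff(std, residues), collapse = ", "))
  }
  class_of <- rep(seq_along(classes), nchar(classes))
  names(class_of) <- residues
  structure(list(classes = classes, class_of = class_of),
            class = "dayhoff_partition")
}

#' Classify an amino-acid substitution as conservative or radical
#'
#' @param aa1,aa2 single-letter residue codes
#' @param partition a [dayhoff_partition()]
#' @return `"conservative"` if both residues share a class, `"radical"`
#'   otherwise
#' @export
classify_substitution <- function(aa1, aa2, partition = dayhoff_partition()) {
  c1 <- partition$class_of[aa1]
  c2 <- partition$class_of[aa2]
  if (any(is.na(c1)) || any(is.na(c2))) {
    bad <- unique(c(aa1[is.na(c1)], aa2[is.na(c2)]))
    stop("residue(s) not covered by partition: ", paste(bad, collapse = ", "))
  }
  unname(ifelse(c1 == c2, "conservative", "radical"))
}

.partition_key <- function(partition) paste(partition$classes, collapse = "|")

# neighbours of a codon obtained by one nucleotide change at one position
.codon_neighbours <- function(codon, pos) {
  nts <- c("A", "C", "G", "T")
  cur <- substr(codon, pos, pos)
  alts <- setdiff(nts, cur)
  vapply(alts, function(n) {
    out <- codon
    substr(out, pos, pos) <- n
    out
  }, character(1), USE.NAMES = FALSE)
}

# Per-codon synonymous / nonsynonymous site fractions (Nei-Gojobori counting).
# Each of the 3 positions contributes up to 1 site, split over the 3 possible
# single-nucleotide changes; changes that create a stop codon are disregarded,
# so a codon can hold fewer than 3 countable sites. Radical/conservative
# nonsynonymous site fractions use the supplied partition.
.site_table <- function(partition = dayhoff_partition()) {
  key <- paste0("sites::", .partition_key(partition))
  if (!is.null(.olf_cache[[key]])) return(.olf_cache[[key]])
  gc <- .genetic_code()
  codons <- .sense_codons()
  out <- matrix(0, nrow = length(codons), ncol = 4,
                dimnames = list(codons, c("S", "N", "N_R", "N_C")))
  for (cod in codons) {
    aa <- gc[[cod]]
    for (pos in 1:3) {
      for (nb in .codon_neighbours(cod, pos)) {
        aa2 <- gc[[nb]]
        if (aa2 == "*") next               # stop mutations are not counted
        if (aa2 == aa) {
          out[cod, "S"] <- out[cod, "S"] + 1 / 3
        } else {
          out[cod, "N"] <- out[cod, "N"] + 1 / 3
          cls <- classify_substitution(aa, aa2, partition)
          col <- if (cls == "radical") "N_R" else "N_C"
          out[cod, col] <- out[cod, col] + 1 / 3
        }
      }
    }
  }
  .olf_cache[[key]] <- out
  out
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# Pathway-averaged difference counts for one sense-codon pair: synonymous and
# nonsynonymous differences, the latter split radical/conservative. Minimal
# mutational pathways (orderings of the differing positions) are enumerated;
# pathways passing through a stop codon are excluded. In the degenerate case
# where every pathway is blocked by stops, all pathways are used and any step
# into or out of a stop codon is scored nonsynonymous-radical.
.pair_path_counts <- function(c1, c2, partition) {
  gc <- .genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(Sd = 0, Nd = 0, O_R = 0, O_C = 0))
  score_path <- function(order, allow_stops) {
    cur <- c1
    counts <- c(Sd = 0, Nd = 0, O_R = 0, O_C = 0)
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      aa1 <- gc[[cur]]; aa2 <- gc[[nxt]]
      if (aa1 == "*" || aa2 == "*") {
        if (!allow_stops) return(NULL)
        counts["Nd"] <- counts["Nd"] + 1
        counts["O_R"] <- counts["O_R"] + 1
      } else if (aa1 == aa2) {
        counts["Sd"] <- counts["Sd"] + 1
      } else {
        counts["Nd"] <- counts["Nd"] + 1
        cls <- classify_substitution(aa1, aa2, partition)
        key <- if (cls == "radical") "O_R" else "O_C"
        counts[key] <- counts[key] + 1
      }
      cur <- nxt
    }
    counts
  }
  orders <- .permutations(pos)
  scored <- Filter(Negate(is.null), lapply(orders, score_path, allow_stops = FALSE))
  if (length(scored) == 0) {
    scored <- lapply(orders, score_path, allow_stops = TRUE)
  }
  Reduce(`+`, scored) / length(scored)
}

# Precomputed difference counts for all sense-codon pairs, cached per
# partition: four 61x61 matrices indexed by codon string.
.pair_tables <- function(partition = dayhoff_partition()) {
  key <- paste0("pairs::", .partition_key(partition))
  if (!is.null(.olf_cache[[key]])) return(.olf_cache[[key]])
  codons <- .sense_codons()
  n <- length(codons)
  tabs <- lapply(c("Sd", "Nd", "O_R", "O_C"), function(x)
    matrix(0, n, n, dimnames = list(codons, codons)))
  names(tabs) <- c("Sd", "Nd", "O_R", "O_C")
  for (i in seq_len(n)) {
    for (j in i:n) {
      cnt <- .pair_path_counts(codons[i], codons[j], partition)
      for (k in names(tabs)) {
        tabs[[k]][i, j] <- cnt[[k]]
        tabs[[k]][j, i] <- cnt[[k]]     # pathway averaging is symmetric
      }
    }
  }
  .olf_cache[[key]] <- tabs
  tabs
}

# Jukes-Cantor correction of a proportion of differences; saturated inputs
# (p >= 3/4) are undefined and returned as NA.
.jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}
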