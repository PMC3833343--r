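# Pseudo-reference construction: substitute fixed interspecific differences
# (filtered SNVs) into a reference genome so that reads of the second
# species can be mapped without reference bias.

#' Apply fixed interspecific differences to a reference
#'
#' Substitutes, in place, the most frequent alternative allele at every
#' single-nucleotide variant passing a minimum read depth and a minimum
#' variant quality. Indels and multi-nucleotide records are skipped with a
#' warning; a variant whose stated reference allele does not match the
#' reference sequence is a hard error (this also guards against applying the
#' same variant set twice). Sequence lengths are never changed.
#'
#' @param reference a named `character` vector or `Biostrings::DNAStringSet`
#' @param variants data frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt` (comma-separated alternative alleles), `qual`, `depth`,
#'   `allele_counts` (comma-separated counts aligned with `alt`)
#' @param min_depth minimum read depth (default 5, inclusive)
#' @param min_quality minimum variant quality (default 60, inclusive)
#' @return list with `reference` (modified, same class as a character
#'   vector), `report` (counts `n_candidates`, `n_indel_skipped`,
#'   `n_pass_depth`, `n_pass_quality`, `n_substituted`) and `sites`
#'   (per-candidate log with the applied allele and tie flag)
#' @export
apply_fixed_differences <- function(reference, variants,
                                    min_depth = 5, min_quality = 60) {
  if (inherits(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  if (is.null(names(reference))) stop("reference sequences must be named")
  ref <- reference
  v <- variants
  n_cand <- nrow(v)
  if (n_cand == 0) {
    return(list(reference = ref,
                report = list(n_candidates = 0L, n_indel_skipped = 0L,
                              n_pass_depth = 0L, n_pass_quality = 0L,
                              n_substituted = 0L),
                sites = data.frame()))
  }
  alts <- strsplit(as.character(v$alt), ",", fixed = TRUE)
  counts <- lapply(strsplit(as.character(v$allele_counts), ",", fixed = TRUE),
                   as.numeric)
  is_snv <- nchar(as.character(v$ref)) == 1 &
    vapply(alts, function(a) all(nchar(a) == 1), logical(1))
  if (any(!is_snv)) {
    warning(sum(!is_snv), " indel/multi-nucleotide record(s) skipped")
  }
  # reference-allele check applies to every SNV record, filtered or not
  for (i in which(is_snv)) {
    chrom <- as.character(v$chrom[i])
    if (!chrom %in% names(ref)) stop("variant on unknown sequence: ", chrom)
    pos <- v$pos[i]
    if (pos < 1 || pos > nchar(ref[[chrom]])) {
      stop("variant position out of range: ", chrom, ":", pos)
    }
    base <- substr(ref[[chrom]], pos, pos)
    if (base != as.character(v$ref[i])) {
      stop("reference mismatch at ", chrom, ":", pos, " (expected ",
           v$ref[i], ", found ", base,
           "); was the variant set already applied?")
    }
  }
  pass_depth <- is_snv & v$depth >= min_depth
  pass_qual <- pass_depth & v$qual >= min_quality
  sites <- data.frame(
    chrom = as.character(v$chrom), pos = v$pos,
    ref = as.character(v$ref),
    is_snv = is_snv, pass_depth = pass_depth, pass_quality = pass_qual,
    applied_allele = NA_character_, tie_broken = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in which(pass_qual)) {
    a <- alts[[i]]
    cnt <- counts[[i]]
    if (length(cnt) != length(a)) {
      stop("allele_counts length does not match alt alleles at row ", i)
    }
    best <- a[cnt == max(cnt)]
    tie <- length(best) > 1
    allele <- sort(best)[1]              # lexicographic tie-break A<C<G<T
    chrom <- as.character(v$chrom[i])
    substr(ref[[chrom]], v$pos[i], v$pos[i]) <- allele
    sites$applied_allele[i] <- allele
    sites$tie_broken[i] <- tie
  }
  stopifnot(all(nchar(ref) == nchar(reference)))
  list(
    reference = ref,
    report = list(
      n_candidates = as.integer(n_cand),
      n_indel_skipped = as.integer(sum(!is_snv)),
      n_pass_depth = as.integer(sum(pass_depth)),
      n_pass_quality = as.integer(sum(pass_qual)),
      n_substituted = as.integer(sum(pass_qual))
    ),
    sites = sites
  )
}

#' Read variant records from a (plain-text) VCF file
#'
#' Minimal reader for the fields the pseudo-reference step consumes: CHROM,
#' POS, REF, ALT, QUAL, and the INFO keys `DP` (read depth) and `AC`
#' (per-alternative allele counts).
#'
#' @param path VCF file (plain text or gzipped)
#' @return data frame in the shape [apply_fixed_differences()] expects
#' @export
read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(fix) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      qual = numeric(), depth = numeric(),
                      allele_counts = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = as.numeric(fix[, "QUAL"]),
    depth = as.numeric(vcfR::extract.info(vcf, "DP")),
    allele_counts = vcfR::extract.info(vcf, "AC"),
    stringsAsFactors = FALSE
  )
}

#' Write variant records as a minimal VCF file
#'
#' @param variants data frame in the shape [apply_fixed_differences()] expects
#' @param path output file
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alt allele counts\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- if (nrow(variants)) {
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
          variants$qual, "PASS",
          paste0("DP=", variants$depth, ";AC=", variants$allele_counts),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a named character reference as FASTA
#'
#' @param reference named character vector of sequences
#' @param path output FASTA
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference), filepath = path)
  invisible(path)
}

#' Read a reference FASTA as a named character vector
#'
#' @param path FASTA file
#' @return named character vector
#' @export
read_reference_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), sub("\\s.*$", "", names(s)))
}
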