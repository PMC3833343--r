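# Synthetic-data generators with recorded ground truth for every pipeline
# stage. The simulators are deliberately simple (uniform codon usage,
# Poisson counts, bootstrap supports fixed at 100): they exercise the
# pipeline's logic with known answers rather than emulate biological
# realism. Every generator is a pure function of its arguments, seed
# included.

#' Simulate a codon-aligned ortholog pair at a known omega
#'
#' Draws an ancestral sequence uniformly over sense codons and evolves two
#' descendants independently. On each branch every codon position proposes a
#' mutation with probability `per_site_rate`; proposals creating a stop
#' codon are rejected, synonymous proposals are always accepted, and
#' nonsynonymous proposals are accepted with probability proportional to
#' `omega`, making the realized nonsynonymous/synonymous rate ratio track
#' `omega`. An accepted nonsynonymous change is radical with probability
#' `radical_bias`: the class is drawn first and a single-nucleotide target
#' of that Dayhoff class is sampled within the codon (events whose drawn
#' class is unavailable in the codon are dropped).
#'
#' @param n_codons number of codons (default 3000)
#' @param omega true dN/dS (>= 0)
#' @param radical_bias probability an accepted nonsynonymous change is
#'   radical (default 0.5)
#' @param per_site_rate per-position proposal probability per branch
#'   (default 0.08, a moderate divergence where multiple hits are rare)
#' @param seed integer seed
#' @param partition a [dayhoff_partition()] used for the radical bias
#' @return list with `pair` (a [prepare_pair()] result) and `truth`
#'   (omega, radical_bias, realized substitution counts)
#' @export
simulate_codon_pair <- function(n_codons = 3000, omega = 0.5,
                                radical_bias = 0.5, per_site_rate = 0.08,
                                seed = 1, partition = dayhoff_partition()) {
  if (omega < 0) stop("omega must be non-negative")
  if (radical_bias < 0 || radical_bias > 1) stop("radical_bias must be in [0,1]")
  gc <- .genetic_code()
  sense <- .sense_codons()
  nts <- c("A", "C", "G", "T")
  truth_counts <- c(syn = 0L, nonsyn = 0L, radical = 0L, conservative = 0L)
  evolve <- function(codons) {
    for (i in seq_along(codons)) {
      for (pos in 1:3) {
        if (runif(1) >= per_site_rate) next
        cur <- codons[i]
        alt <- sample(setdiff(nts, substr(cur, pos, pos)), 1)
        prop <- cur
        substr(prop, pos, pos) <- alt
        aa1 <- gc[[cur]]; aa2 <- gc[[prop]]
        if (aa2 == "*") next                      # stop proposals rejected
        if (aa1 == aa2) {
          codons[i] <- prop
          truth_counts["syn"] <<- truth_counts["syn"] + 1L
        } else if (runif(1) < omega) {
          # draw the physicochemical class of the accepted change first and
          # sample a single-nucleotide target of that class anywhere in the
          # codon; when the codon offers no change of the drawn class the
          # event is dropped, so accepted changes carry the planted class
          # frequency faithfully
          want_radical <- runif(1) < radical_bias
          cands <- unlist(lapply(1:3, .codon_neighbours, codon = cur))
          cand_aa <- unname(gc[cands])
          ok <- cand_aa != "*" & cand_aa != aa1
          cands <- cands[ok]; cand_aa <- cand_aa[ok]
          cls <- classify_substitution(rep(aa1, length(cand_aa)), cand_aa,
                                       partition)
          pick_from <- if (want_radical) cands[cls == "radical"] else
            cands[cls == "conservative"]
          if (length(pick_from) == 0) next
          chosen <- if (length(pick_from) == 1) pick_from else sample(pick_from, 1)
          codons[i] <- chosen
          realized <- classify_substitution(aa1, gc[[chosen]], partition)
          truth_counts["nonsyn"] <<- truth_counts["nonsyn"] + 1L
          truth_counts[realized] <<- truth_counts[realized] + 1L
        }
      }
    }
    codons
  }
  with_seed(seed, {
    ancestor <- sample(sense, n_codons, replace = TRUE)
    a <- evolve(ancestor)
    b <- evolve(ancestor)
  })
  pair <- prepare_pair(paste(a, collapse = ""), paste(b, collapse = ""),
                       gene_id_a = "sim_a", gene_id_b = "sim_b",
                       species_a = "gambiae", species_b = "quad")
  list(pair = pair,
       truth = list(omega = omega, radical_bias = radical_bias,
                    per_site_rate = per_site_rate,
                    counts = as.list(truth_counts)))
}

#' Simulate a two-sample count table with planted differential expression
#'
#' Gene-wise true rates are log-normal around `mean_depth`; a `de_fraction`
#' of genes get a symmetric shift of `effect_log2fc` (half up in each
#' species) and counts are Poisson. Library sizes are the nominal
#' `n_genes * mean_depth`.
#'
#' @param n_genes number of genes (default 2000)
#' @param de_fraction fraction of genes differentially expressed (default
#'   0.5: in antennal chemosensory repertoires the majority of detectable
#'   genes differ in abundance between the sibling species)
#' @param effect_log2fc absolute true log2 fold change of DE genes
#'   (default 2)
#' @param mean_depth mean read count per gene (default 200)
#' @param seed integer seed
#' @return list with `counts` (gene_id, count_a, count_b, length), `lib_a`,
#'   `lib_b`, and `truth` (per-gene true log2fc and DE flag)
#' @export
simulate_counts <- function(n_genes = 2000, de_fraction = 0.5,
                            effect_log2fc = 2, mean_depth = 200, seed = 1) {
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0,1]")
  with_seed(seed, {
    base <- rlnorm(n_genes, meanlog = log(mean_depth), sdlog = 0.25)
    n_de <- round(de_fraction * n_genes)
    de <- rep(FALSE, n_genes)
    de[sample.int(n_genes, n_de)] <- TRUE
    sign <- ifelse(de, sample(c(-1, 1), n_genes, replace = TRUE), 0)
    true_lfc <- sign * effect_log2fc
    rate_a <- base * 2^(-true_lfc / 2)
    rate_b <- base * 2^(true_lfc / 2)
    counts <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      count_a = rpois(n_genes, rate_a),
      count_b = rpois(n_genes, rate_b),
      length = sample(500:3000, n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  lib <- n_genes * mean_depth
  list(counts = counts, lib_a = lib, lib_b = lib,
       truth = data.frame(gene_id = counts$gene_id, is_de = de,
                          true_log2fc = true_lfc, stringsAsFactors = FALSE))
}

#' Simulate a forest of ortholog-group gene trees with known events
#'
#' Each orthologous group starts from one ancestral gene. With probability
#' `p_gain` a randomly chosen species gains one extra copy; with probability
#' `p_loss` one species (never the one that gained) loses its gene. Trees
#' are emitted with all bootstrap supports at 100 — one tree per OG, with
#' single-gene OGs as one-leaf trees.
#'
#' @param n_OGs number of orthologous groups (default 500)
#' @param p_gain per-OG gain probability (default 0.15)
#' @param p_loss per-OG loss probability (default 0.1)
#' @param species length-2 species labels
#' @param seed integer seed
#' @return list with `trees` (list of `ape::phylo` or single gene ids),
#'   `species_map` (data frame gene/species) and `truth` (per-OG event
#'   counts and memberships)
#' @export
simulate_gene_trees <- function(n_OGs = 500, p_gain = 0.15, p_loss = 0.1,
                                species = c("gambiae", "quad"), seed = 1) {
  stopifnot(p_gain >= 0, p_gain <= 1, p_loss >= 0, p_loss <= 1)
  trees <- vector("list", n_OGs)
  truth <- vector("list", n_OGs)
  map <- list()
  with_seed(seed, {
    for (i in seq_len(n_OGs)) {
      gains <- c(0L, 0L)
      losses <- c(0L, 0L)
      gain_sp <- 0L
      if (runif(1) < p_gain) {
        gain_sp <- sample(1:2, 1)
        gains[gain_sp] <- 1L
      }
      if (runif(1) < p_loss) {
        loss_cand <- setdiff(1:2, gain_sp)
        loss_sp <- if (length(loss_cand) == 1) loss_cand else sample(loss_cand, 1)
        losses[loss_sp] <- 1L
      }
      n_copies <- 1L + gains - losses
      genes <- lapply(1:2, function(s) {
        if (n_copies[s] == 0) character(0) else
          sprintf("%s_og%03d_%d", species[s], i, seq_len(n_copies[s]))
      })
      block <- function(g) {
        if (length(g) == 1) g else paste0("(", paste(g, collapse = ","), ")100")
      }
      nwk <- if (all(n_copies > 0)) {
        paste0("(", block(genes[[1]]), ",", block(genes[[2]]), ")100;")
      } else {
        g <- c(genes[[1]], genes[[2]])
        if (length(g) == 1) paste0("(", g, ");") else
          paste0("(", paste(g, collapse = ","), ")100;")
      }
      tr <- ape::read.tree(text = nwk)
      trees[[i]] <- if (length(tr$tip.label) == 1) tr$tip.label else tr
      truth[[i]] <- list(members_a = genes[[1]], members_b = genes[[2]],
                         gains_a = gains[1], gains_b = gains[2],
                         losses_a = losses[1], losses_b = losses[2])
      map[[i]] <- data.frame(
        gene = c(genes[[1]], genes[[2]]),
        species = c(rep(species[1], length(genes[[1]])),
                    rep(species[2], length(genes[[2]]))),
        stringsAsFactors = FALSE
      )
    }
  })
  list(trees = trees, species_map = do.call(rbind, map), truth = truth)
}

#' Simulate a sparse receptor-odorant response matrix with a planted bias
#'
#' Each receptor responds strongly (well above the robustness threshold) to
#' a `tuning_sparsity` fraction of odorants; all other cells are small,
#' sometimes negative. Odorants carry a chemical class and a
#' human-association flag. A subset of receptors are "specialists" for the
#' `biased_class`: their tuned odorants are drawn mostly from that class and
#' their abundance is tilted `bias_fold`-fold toward the first species, so
#' that class is the planted enrichment the analysis should recover.
#'
#' @param n_receptors,n_odorants matrix dimensions (defaults 45 x 48)
#' @param tuning_sparsity fraction of odorants each receptor is tuned to
#'   (default 0.2)
#' @param response_scale center of strong responses in delta spikes/s
#'   (default 250)
#' @param biased_class chemical class given the species-biased weighting
#'   (default "ester")
#' @param bias_fold abundance fold-bias of specialist receptors between the
#'   species (default 4)
#' @param seed integer seed
#' @return list with `matrix`, `meta` (odorant, class, human_associated),
#'   `rpkm_g`, `rpkm_q` (named per-receptor abundances) and `truth`
#' @export
simulate_response_matrix <- function(n_receptors = 45, n_odorants = 48,
                                     tuning_sparsity = 0.2,
                                     response_scale = 250,
                                     biased_class = "ester", bias_fold = 4,
                                     seed = 1) {
  stopifnot(tuning_sparsity >= 0, tuning_sparsity <= 1)
  classes <- c("ester", "alcohol", "aromatic", "ketone", "indole", "terpene")
  with_seed(seed, {
    receptors <- sprintf("Or%02d", seq_len(n_receptors))
    odorants <- sprintf("odorant%02d", seq_len(n_odorants))
    # deorphanization panels are ester-rich: a quarter of the panel, the
    # rest spread over the remaining classes
    n_ester <- ceiling(n_odorants / 4)
    class_of <- setNames(c(rep("ester", n_ester),
                           rep(classes[-1], length.out = n_odorants - n_ester)),
                         odorants)
    human <- setNames(runif(n_odorants) < 0.4, odorants)
    m <- matrix(rnorm(n_receptors * n_odorants, 0, 20),
                n_receptors, n_odorants,
                dimnames = list(receptors, odorants))
    specialist <- seq_len(n_receptors) <= ceiling(n_receptors / 3)
    # specialists are narrowly tuned: essentially silent off-class, so their
    # biased weighting cannot leak outside the planted class
    m[specialist, ] <- rnorm(sum(specialist) * n_odorants, 0, 5)
    n_tuned <- ceiling(tuning_sparsity * n_odorants)
    in_class <- which(class_of == biased_class)
    out_class <- which(class_of != biased_class)
    for (r in seq_len(n_receptors)) {
      if (n_tuned == 0) break
      if (specialist[r] && length(in_class) > 0) {
        # specialists are tuned exclusively within the biased class, so the
        # planted species bias stays confined to that class
        tuned <- sample(in_class, min(n_tuned, length(in_class)))
      } else {
        tuned <- sample(out_class, min(n_tuned, length(out_class)))
      }
      m[r, tuned] <- runif(length(tuned), response_scale * 0.6,
                           response_scale * 1.6)
    }
    base <- rlnorm(n_receptors, log(50), 0.5)
    # background receptors come in antithetic pairs — equal baseline
    # abundance, exactly mirrored species tilts — so the non-planted
    # classes are symmetric by construction and only the planted class
    # carries an aggregate species bias
    n_bg <- sum(!specialist)
    mag <- abs(rnorm(ceiling(n_bg / 2), 0, 0.5))
    eps <- as.vector(rbind(mag, -mag))[seq_len(n_bg)]
    bg_base <- rep(rlnorm(ceiling(n_bg / 2), log(50), 0.5), each = 2)[seq_len(n_bg)]
    base[!specialist] <- bg_base
    tilt <- numeric(n_receptors)
    tilt[specialist] <- log2(bias_fold) / 2
    tilt[!specialist] <- eps
    rpkm_g <- setNames(base * 2^tilt, receptors)
    rpkm_q <- setNames(base * 2^(-tilt), receptors)
  })
  list(
    matrix = m,
    meta = data.frame(odorant = odorants, class = unname(class_of),
                      human_associated = unname(human),
                      stringsAsFactors = FALSE),
    rpkm_g = rpkm_g, rpkm_q = rpkm_q,
    truth = list(biased_class = biased_class, bias_fold = bias_fold,
                 specialist_receptors = receptors[specialist])
  )
}

#' Simulate a reference and a variant set spanning the filter boundaries
#'
#' Generates a random reference, then SNV records whose depths and qualities
#' straddle the depth/quality filters, plus a few indel records that must be
#' skipped. Truth records exactly which sites a correct pseudo-reference
#' step substitutes and with which allele.
#'
#' @param n_seqs,seq_length reference shape (defaults 2 x 5000)
#' @param n_variants number of SNV records (default 60)
#' @param n_indels number of indel records to sprinkle in (default 3)
#' @param depth_range,quality_range inclusive integer ranges the depths and
#'   qualities are drawn from; defaults span the conventional depth-5 /
#'   quality-60 cutoffs
#' @param min_depth,min_quality the filter the truth is computed against
#' @param seed integer seed
#' @return list with `reference` (named character), `variants` (data frame),
#'   and `truth` (data frame of sites that must be substituted, with the
#'   expected allele)
#' @export
simulate_variants <- function(n_seqs = 2, seq_length = 5000, n_variants = 60,
                              n_indels = 3, depth_range = c(1, 10),
                              quality_range = c(30, 90),
                              min_depth = 5, min_quality = 60, seed = 1) {
  nts <- c("A", "C", "G", "T")
  with_seed(seed, {
    reference <- setNames(
      vapply(seq_len(n_seqs), function(i)
        paste(sample(nts, seq_length, replace = TRUE), collapse = ""),
        character(1)),
      sprintf("chr%d", seq_len(n_seqs)))
    rows <- vector("list", n_variants + n_indels)
    used <- list()
    pick_site <- function() {
      repeat {
        chrom <- sample(names(reference), 1)
        pos <- sample.int(seq_length, 1)
        key <- paste(chrom, pos)
        if (is.null(used[[key]])) {
          used[[key]] <<- TRUE
          return(list(chrom = chrom, pos = pos))
        }
      }
    }
    for (i in seq_len(n_variants)) {
      s <- pick_site()
      ref_base <- substr(reference[[s$chrom]], s$pos, s$pos)
      n_alt <- sample(1:2, 1, prob = c(0.7, 0.3))
      alt <- sample(setdiff(nts, ref_base), n_alt)
      cnt <- sample(1:12, n_alt, replace = TRUE)
      rows[[i]] <- data.frame(
        chrom = s$chrom, pos = s$pos, ref = ref_base,
        alt = paste(alt, collapse = ","),
        qual = sample(quality_range[1]:quality_range[2], 1),
        depth = sample(depth_range[1]:depth_range[2], 1),
        allele_counts = paste(cnt, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
    for (i in seq_len(n_indels)) {
      s <- pick_site()
      ref_base <- substr(reference[[s$chrom]], s$pos, s$pos)
      rows[[n_variants + i]] <- data.frame(
        chrom = s$chrom, pos = s$pos, ref = ref_base,
        alt = paste0(ref_base, sample(nts, 1)),     # insertion record
        qual = sample(quality_range[1]:quality_range[2], 1),
        depth = sample(depth_range[1]:depth_range[2], 1),
        allele_counts = "5",
        stringsAsFactors = FALSE
      )
    }
  })
  variants <- do.call(rbind, rows)
  variants <- variants[order(variants$chrom, variants$pos), ]
  rownames(variants) <- NULL
  is_snv <- nchar(variants$ref) == 1 &
    !grepl("[^ACGT,]", variants$alt) &
    vapply(strsplit(variants$alt, ","), function(a) all(nchar(a) == 1),
           logical(1))
  pass <- is_snv & variants$depth >= min_depth & variants$qual >= min_quality
  expected_allele <- vapply(seq_len(nrow(variants)), function(i) {
    if (!pass[i]) return(NA_character_)
    a <- strsplit(variants$alt[i], ",")[[1]]
    cnt <- as.numeric(strsplit(variants$allele_counts[i], ",")[[1]])
    sort(a[cnt == max(cnt)])[1]
  }, character(1))
  list(
    reference = reference,
    variants = variants,
    truth = data.frame(chrom = variants$chrom, pos = variants$pos,
                       must_substitute = pass,
                       expected_allele = expected_allele,
                       stringsAsFactors = FALSE)
  )
}
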