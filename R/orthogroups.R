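# Orthologous-group delineation and gene gain/loss reconciliation from
# bootstrap-annotated two-species gene trees. An orthologous group (OG) is a
# highly supported clade interpreted as a single gene in the most recent
# common ancestor of the two species; within an OG, extra copies in one
# species are gains on that species' branch and absence of a species is a
# single loss.

.tree_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

.tree_clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[[1]]
    stack <- stack[-1]
    kids <- .tree_children(tree, cur)
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

.node_support <- function(tree, node) {
  ntip <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab)) return(NA_real_)
  val <- suppressWarnings(as.numeric(lab[node - ntip]))
  val
}

# do the tips `tips` (tree indices) form a clade of the tree?
.is_monophyletic_set <- function(tree, tips) {
  if (length(tips) <= 1) return(TRUE)
  mrca <- ape::getMRCA(tree, tips)
  length(.tree_clade_tips(tree, mrca)) == length(tips)
}

.make_og <- function(members_a, members_b) {
  na <- length(members_a)
  nb <- length(members_b)
  list(
    members_a = members_a, members_b = members_b,
    ancestral_copies = 1L,
    gains_a = max(na - 1L, 0L), gains_b = max(nb - 1L, 0L),
    losses_a = as.integer(na == 0L), losses_b = as.integer(nb == 0L)
  )
}

#' Delineate orthologous groups from a two-species gene tree
#'
#' Partitions the leaves of a gene tree into orthologous groups. A clade
#' qualifies as one OG when its bootstrap support exceeds
#' `support_threshold` (strictly; nodes without a support value, such as the
#' root, are treated as supported) and its gene content is consistent with a
#' single ancestral gene: either one gene of each species (a 1:1 ortholog
#' pair), or k > 1 genes of one species forming a monophyletic block together
#' with at most one gene of the other species (k - 1 lineage-specific gains,
#' plus one loss if the other species is absent). Clades that fail either
#' condition are descended into; multifurcations are treated as unresolved
#' and descended through. A leaf reached this way becomes a singleton OG
#' scored as ancestral-present with one loss in the absent species.
#'
#' @param tree an `ape::phylo` gene tree with bootstrap values in
#'   `node.label`, or a single gene identifier (a one-gene family)
#' @param species_map data frame with columns `gene` and `species` mapping
#'   every leaf to one of two species
#' @param support_threshold bootstrap percentage a clade must exceed
#'   (default 90)
#' @param species optional length-2 character vector fixing which species is
#'   "a" and which is "b"; defaults to the sorted unique species of the map
#' @param midpoint_root if `TRUE`, midpoint-root the tree first (RAxML trees
#'   are unrooted; rooting changes which clades exist)
#' @return list of orthologous groups, each with `members_a`, `members_b`,
#'   `ancestral_copies` (always 1), `gains_a`, `gains_b`, `losses_a`,
#'   `losses_b`
#' @export
delineate_orthogroups <- function(tree, species_map, support_threshold = 90,
                                  species = NULL, midpoint_root = FALSE) {
  if (!all(c("gene", "species") %in% names(species_map))) {
    stop("species_map needs columns 'gene' and 'species'")
  }
  sp_of <- setNames(as.character(species_map$species),
                    as.character(species_map$gene))
  if (is.null(species)) species <- sort(unique(unname(sp_of)))
  if (length(species) > 2) stop("more than two species in species_map")
  if (length(species) == 1) species <- c(species, paste0(species, "_absent"))

  og_from_genes <- function(genes) {
    sp <- sp_of[genes]
    if (anyNA(sp)) {
      stop("unmapped leaf: ", paste(genes[is.na(sp)], collapse = ", "))
    }
    .make_og(genes[sp == species[1]], genes[sp == species[2]])
  }

  if (is.character(tree)) {          # degenerate single-gene family
    return(list(og_from_genes(tree)))
  }
  stopifnot(inherits(tree, "phylo"))
  if (midpoint_root && length(tree$tip.label) > 2) {
    tree <- phangorn::midpoint(tree)
  }
  if (anyNA(sp_of[tree$tip.label])) {
    bad <- tree$tip.label[is.na(sp_of[tree$tip.label])]
    stop("unmapped leaf: ", paste(bad, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  if (ntip == 1) return(list(og_from_genes(tree$tip.label)))

  ogs <- list()
  recurse <- function(node) {
    if (node <= ntip) {
      ogs[[length(ogs) + 1]] <<- og_from_genes(tree$tip.label[node])
      return(invisible())
    }
    kids <- .tree_children(tree, node)
    tips <- .tree_clade_tips(tree, node)
    genes <- tree$tip.label[tips]
    sp <- sp_of[genes]
    na <- sum(sp == species[1])
    nb <- sum(sp == species[2])
    support <- .node_support(tree, node)
    supported <- is.na(support) || support > support_threshold
    binary <- length(kids) == 2
    consistent <- FALSE
    if (min(na, nb) <= 1 && max(na, nb) >= 1) {
      # the multi-copy species' genes must be a clade (duplications after
      # the species split); trivially true when no species has >1 copy here
      consistent <- TRUE
      if (max(na, nb) > 1) {
        multi_sp <- if (na > nb) species[1] else species[2]
        consistent <- .is_monophyletic_set(tree, tips[sp == multi_sp])
      }
    }
    if (binary && supported && consistent) {
      ogs[[length(ogs) + 1]] <<- og_from_genes(genes)
    } else {
      for (k in kids) recurse(k)
    }
    invisible()
  }
  root <- ntip + 1L
  recurse(root)
  ogs
}

#' Delineate orthologous groups across a forest of gene trees
#'
#' @param trees list of `ape::phylo` objects and/or single gene identifiers
#' @inheritParams delineate_orthogroups
#' @return flat list of orthologous groups over all trees
#' @export
delineate_forest <- function(trees, species_map, support_threshold = 90,
                             species = NULL, midpoint_root = FALSE) {
  unlist(lapply(trees, delineate_orthogroups, species_map = species_map,
                support_threshold = support_threshold, species = species,
                midpoint_root = midpoint_root),
         recursive = FALSE)
}

.check_og <- function(og) {
  ok_a <- length(og$members_a) == og$ancestral_copies + og$gains_a - og$losses_a
  ok_b <- length(og$members_b) == og$ancestral_copies + og$gains_b - og$losses_b
  if (!ok_a || !ok_b) {
    stop("inconsistent orthologous group: member counts do not equal ",
         "ancestral copies + gains - losses")
  }
  invisible(og)
}

#' Summarize ortholog-group sets into a gene-repertoire table
#'
#' Aggregates per-family lists of orthologous groups into per-family gene
#' counts for each species, the ancestral (MRCA) gene count (= number of
#' OGs), and the total gains and losses on each species branch. The
#' bookkeeping identity count_s = n_OGs + gains_s - losses_s is enforced.
#'
#' @param og_sets named list: family name -> list of orthologous groups
#' @return data frame with one row per family plus a `total` row
#' @export
summarize_repertoire <- function(og_sets) {
  if (length(og_sets) == 0) stop("no ortholog-group sets supplied")
  if (is.null(names(og_sets))) names(og_sets) <- paste0("family", seq_along(og_sets))
  rows <- lapply(names(og_sets), function(fam) {
    ogs <- og_sets[[fam]]
    if (length(ogs) == 0) stop("empty OG set for family ", fam)
    lapply(ogs, .check_og)
    data.frame(
      family = fam,
      n_OGs = length(ogs),
      count_a = sum(vapply(ogs, function(o) length(o$members_a), integer(1))),
      count_b = sum(vapply(ogs, function(o) length(o$members_b), integer(1))),
      gains_a = sum(vapply(ogs, function(o) o$gains_a, numeric(1))),
      gains_b = sum(vapply(ogs, function(o) o$gains_b, numeric(1))),
      losses_a = sum(vapply(ogs, function(o) o$losses_a, numeric(1))),
      losses_b = sum(vapply(ogs, function(o) o$losses_b, numeric(1))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  stopifnot(all(out$count_a == out$n_OGs + out$gains_a - out$losses_a),
            all(out$count_b == out$n_OGs + out$gains_b - out$losses_b))
  total <- out[1, , drop = FALSE]
  total$family <- "total"
  for (col in names(out)[-1]) total[[col]] <- sum(out[[col]])
  rbind(out, total)
}

#' Orthologous groups as a one-row-per-OG data frame
#'
#' @param ogs list of orthologous groups from [delineate_orthogroups()]
#' @return data frame with member lists collapsed by `,`
#' @export
og_table <- function(ogs) {
  do.call(rbind, lapply(seq_along(ogs), function(i) {
    o <- ogs[[i]]
    data.frame(
      og = i,
      members_a = paste(o$members_a, collapse = ","),
      members_b = paste(o$members_b, collapse = ","),
      n_a = length(o$members_a), n_b = length(o$members_b),
      gains_a = o$gains_a, gains_b = o$gains_b,
      losses_a = o$losses_a, losses_b = o$losses_b,
      stringsAsFactors = FALSE
    )
  }))
}

#' Read a forest of support-annotated gene trees from a newick file
#'
#' One tree per line; single-gene families may be written as `(gene);`.
#'
#' @param path newick file
#' @return list of `ape::phylo` objects (single-tip trees are returned as
#'   the gene identifier string)
#' @export
read_gene_trees <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    tr <- ape::read.tree(text = l)
    if (is.null(tr)) stop("could not parse newick: ", l)
    if (length(tr$tip.label) == 1) tr$tip.label else tr
  })
}
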