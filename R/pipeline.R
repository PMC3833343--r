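# Thin orchestration: read a configuration, run whichever stages have
# inputs, write the per-stage tables and a provenance block. No analysis
# logic lives here; every stage is an independently callable function.

#' Default pipeline configuration
#'
#' All thresholds of the analysis with their conventional defaults:
#' bootstrap support 90, response robustness 100 spikes/s, no-change band
#' 10 percent, variant depth 5 and quality 60, fold-change credibility 0.99.
#'
#' @param out_dir output directory
#' @param seed integer seed used by every stochastic step
#' @return named list, serializable losslessly to YAML
#' @export
default_config <- function(out_dir = "olfdiverge_out", seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    thresholds = list(
      support = 90,
      response = 100,
      band_percent = 10,
      min_depth = 5,
      min_quality = 60,
      credibility = 0.99
    ),
    draws = 1e5,
    inputs = list(
      pair_fastas = NULL,       # character vector of two-record FASTAs
      regions_tsv = NULL,       # gene_id \t per-residue label string
      gene_trees = NULL,        # newick forest
      species_map_tsv = NULL,
      counts_tsv = NULL,        # gene_id, count_a, count_b, length
      lib_a = NULL, lib_b = NULL,
      reference_fasta = NULL,
      variants_vcf = NULL,
      response_matrix_tsv = NULL,
      odorant_meta_tsv = NULL,
      rpkm_g_tsv = NULL,        # receptor \t rpkm
      rpkm_q_tsv = NULL
    )
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file
#' @return for `read_config`, the configuration list
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config configuration list
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.read_region_tsv <- function(path) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  setNames(lapply(d[[2]], function(s) strsplit(s, "")[[1]]), d[[1]])
}

#' Run the end-to-end comparative analysis
#'
#' Executes, in dependency order, whichever stages have inputs configured:
#' pseudo-reference substitution, expression (RPKM + reliable fold change),
#' sequence divergence, orthologous groups, and the receptivity model.
#' Missing inputs skip a stage with a warning; any stage error aborts with a
#' stage-tagged message. Tables are written to `config$out_dir` as TSV/JSON
#' and the assembled report (with a provenance block: config hash, seed,
#' package version) is returned invisibly.
#'
#' @param config a configuration list from [default_config()] (or
#'   [read_config()]), with input paths filled in
#' @return the report list, invisibly
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  inp <- config$inputs
  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("olfdiverge")),
    seed = config$seed,
    config_hash = .config_hash(config)
  ))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  tsv <- function(d, file) {
    write.table(d, file.path(out_dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if (!is.null(inp$reference_fasta) && !is.null(inp$variants_vcf)) {
    report$pseudoref <- stage("pseudoref", {
      ref <- read_reference_fasta(inp$reference_fasta)
      variants <- read_variants_vcf(inp$variants_vcf)
      res <- apply_fixed_differences(ref, variants,
                                     min_depth = th$min_depth,
                                     min_quality = th$min_quality)
      write_reference_fasta(res$reference,
                            file.path(out_dir, "pseudo_reference.fasta"))
      jsonlite::write_json(res$report,
                           file.path(out_dir, "pseudoref_report.json"),
                           auto_unbox = TRUE)
      res$report
    })
  } else {
    warning("pseudoref inputs missing; stage skipped")
  }

  if (!is.null(inp$counts_tsv)) {
    report$expression <- stage("expression", {
      counts <- read.delim(inp$counts_tsv, stringsAsFactors = FALSE)
      fc <- fold_change_table(counts, inp$lib_a, inp$lib_b,
                              c = th$credibility, draws = config$draws,
                              seed = config$seed)
      tsv(fc, "fold_change.tsv")
      list(n_genes = nrow(fc), n_significant = sum(fc$significant))
    })
  } else {
    warning("expression inputs missing; stage skipped")
  }

  if (!is.null(inp$pair_fastas)) {
    report$divergence <- stage("divergence", {
      pairs <- lapply(inp$pair_fastas, read_pair_fasta)
      regions <- if (!is.null(inp$regions_tsv)) .read_region_tsv(inp$regions_tsv)
      tab <- divergence_table(pairs, regions_by_gene = regions)
      tsv(tab, "divergence.tsv")
      list(n_pairs = nrow(tab),
           median_omega = median(tab$omega, na.rm = TRUE))
    })
  } else {
    warning("divergence inputs missing; stage skipped")
  }

  if (!is.null(inp$gene_trees) && !is.null(inp$species_map_tsv)) {
    report$orthogroups <- stage("orthogroups", {
      trees <- read_gene_trees(inp$gene_trees)
      smap <- read.delim(inp$species_map_tsv, stringsAsFactors = FALSE)
      ogs <- delineate_forest(trees, smap, support_threshold = th$support)
      tsv(og_table(ogs), "orthogroups.tsv")
      summ <- summarize_repertoire(list(all = ogs))
      jsonlite::write_json(summ, file.path(out_dir, "repertoire_summary.json"))
      summ
    })
  } else {
    warning("orthogroup inputs missing; stage skipped")
  }

  if (!is.null(inp$response_matrix_tsv) && !is.null(inp$odorant_meta_tsv) &&
      !is.null(inp$rpkm_g_tsv) && !is.null(inp$rpkm_q_tsv)) {
    report$receptivity <- stage("receptivity", {
      m <- as.matrix(read.delim(inp$response_matrix_tsv, row.names = 1,
                                check.names = FALSE))
      meta <- read.delim(inp$odorant_meta_tsv, stringsAsFactors = FALSE)
      read_rpkm <- function(p) {
        d <- read.delim(p, stringsAsFactors = FALSE)
        setNames(d[[2]], d[[1]])
      }
      fm <- filter_matrix(m, threshold = th$response)
      prof_g <- compute_receptivity(fm, read_rpkm(inp$rpkm_g_tsv), "gambiae")
      prof_q <- compute_receptivity(fm, read_rpkm(inp$rpkm_q_tsv), "quad")
      changes <- receptivity_change(prof_g, prof_q, band = th$band_percent)
      idx <- match(changes$odorant, meta$odorant)
      changes$class <- meta$class[idx]
      changes$human_associated <- meta$human_associated[idx]
      tsv(changes, "receptivity_change.tsv")
      enr <- rbind(class_enrichment(changes, meta, "chemical_class"),
                   class_enrichment(changes, meta, "human_associated"))
      jsonlite::write_json(enr, file.path(out_dir, "enrichment_tests.json"))
      list(changes = changes, enrichment = enr)
    })
  } else {
    warning("receptivity inputs missing; stage skipped")
  }

  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(report)
}
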