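## End-to-end orchestration: run the enabled stages in dependency order
## from one declarative configuration, write per-stage TSVs, and return a
## run report.

#' Default pipeline configuration
#'
#' Thresholds default to the study-wide values used throughout the
#' package: domain E-value 1e-5, RPKM expression threshold 5, FDR 0.05,
#' fold-change 2, Ks cutoff 3, bootstrap support 70, flank 5000 bp,
#' mu 1e-8.
#'
#' @return Named list of defaults; input paths are `NULL` until set.
#' @export
default_config <- function() {
  list(
    species_tsv = NULL, hits_tsv = NULL, proteins_tsv = NULL,
    orthogroups_tsv = NULL, pairs_fasta = NULL, counts_tsv = NULL,
    libs_tsv = NULL, lengths_tsv = NULL, tree_nwk = NULL,
    kingdoms_tsv = NULL, te_gff = NULL, genes_gff = NULL,
    contigs_tsv = NULL,
    e_value = 1e-5, rpkm_threshold = 5, fdr = 0.05, fc = 2,
    ks_cutoff = 3, ks_exception_species = character(),
    support = 70, flank = 5000, mu = 1e-8, alpha = 0.05,
    stages = c("identify", "cnv", "kaks", "fates", "hgt", "te"),
    outdir = NULL, seed = 1
  )
}

#' Load a pipeline configuration from YAML
#'
#' Unset keys fall back to [default_config()]; unknown keys are an error
#' (typo protection).
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(user)] <- user
  cfg
}

stage_inputs <- function() {
  list(
    identify = c("hits_tsv", "proteins_tsv"),
    cnv = c("orthogroups_tsv", "species_tsv"),
    kaks = "pairs_fasta",
    fates = c("pairs_fasta", "counts_tsv", "libs_tsv", "lengths_tsv"),
    hgt = c("tree_nwk", "kingdoms_tsv"),
    te = c("te_gff", "genes_gff", "contigs_tsv")
  )
}

#' Run the pipeline
#'
#' Executes the enabled stages in dependency order (identify, then
#' cnv/kaks/fates, then hgt/te), writing one TSV per stage into
#' `config$outdir`. All required inputs are checked before any stage runs.
#' Warnings are collected into the report rather than aborting a run; a
#' stage producing zero records is an error.
#'
#' @param config Configuration list (see [default_config()]) or the path
#'   to a YAML file.
#' @return The run report: data.frame with one row per executed stage
#'   (`stage`, `n_records`, `output`, `warnings`), with the full parameter
#'   echo in attribute `"config"`. Also written to
#'   `<outdir>/run_report.tsv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- default_config()
  cfg[names(config)] <- config
  if (is.null(cfg$outdir)) stop("config$outdir is required")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  order_all <- c("identify", "cnv", "kaks", "fates", "hgt", "te")
  stages <- intersect(order_all, cfg$stages)
  if (length(stages) == 0L) stop("no stages enabled")
  needs <- stage_inputs()
  for (st in stages) {
    for (key in needs[[st]]) {
      if (is.null(cfg[[key]])) {
        stop("stage '", st, "' is enabled but config$", key, " is not set")
      }
      if (!file.exists(cfg[[key]])) {
        stop("stage '", st, "' input does not exist: ", cfg[[key]])
      }
    }
  }

  report <- list()
  run_stage <- function(name, fun) {
    warns <- character()
    res <- withCallingHandlers(
      fun(),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    if (res$n == 0L) stop("stage '", name, "' produced zero records")
    message(sprintf("[%s] %d records -> %s", name, res$n, res$out))
    report[[name]] <<- data.frame(
      stage = name, n_records = res$n, output = res$out,
      warnings = paste(warns, collapse = "; "),
      stringsAsFactors = FALSE
    )
  }

  out_path <- function(f) file.path(cfg$outdir, f)

  if ("identify" %in% stages) {
    run_stage("identify", function() {
      hits <- read_domain_hits(cfg$hits_tsv, "simple_tsv")
      prot <- read_tsv_file(cfg$proteins_tsv)
      fam <- build_family_table(hits, prot, e_threshold = cfg$e_value)
      write_tsv_file(fam, out_path("myb_genes.tsv"))
      list(n = nrow(fam), out = out_path("myb_genes.tsv"))
    })
  }
  if ("cnv" %in% stages) {
    run_stage("cnv", function() {
      og <- read_orthogroups(cfg$orthogroups_tsv)
      meta <- read_species_table(cfg$species_tsv)
      cn <- copy_number_matrix(og, meta$species_id)
      res <- flag_divergent_orthogroups(cn, meta, alpha = cfg$alpha)
      write_tsv_file(res, out_path("cnv_tests.tsv"))
      list(n = nrow(res), out = out_path("cnv_tests.tsv"))
    })
  }
  kaks_res <- NULL
  if ("kaks" %in% stages) {
    run_stage("kaks", function() {
      pairs <- read_pair_cds(cfg$pairs_fasta)
      res <- kaks_table(pairs)
      kaks_res <<- res
      write_tsv_file(res, out_path("kaks.tsv"))
      list(n = nrow(res), out = out_path("kaks.tsv"))
    })
  }
  if ("fates" %in% stages) {
    run_stage("fates", function() {
      pairs <- read_pair_cds(cfg$pairs_fasta)[, c("gene_a", "gene_b")]
      counts_df <- read_tsv_file(cfg$counts_tsv)
      counts <- as.matrix(counts_df[, -1L, drop = FALSE])
      rownames(counts) <- counts_df[[1L]]
      libs <- read_tsv_file(cfg$libs_tsv)
      lens_df <- read_tsv_file(cfg$lengths_tsv)
      lens <- stats::setNames(lens_df$length, lens_df$gene_id)
      tests <- suppressMessages(test_duplicate_pairs(
        pairs, counts, libs, lens,
        fdr_alpha = cfg$fdr, fc_cutoff = cfg$fc,
        rpkm_threshold = cfg$rpkm_threshold
      ))
      fates <- classify_fates(tests)
      write_tsv_file(tests, out_path("pair_tests.tsv"))
      write_tsv_file(fates, out_path("fates.tsv"))
      list(n = nrow(fates), out = out_path("fates.tsv"))
    })
  }
  if ("hgt" %in% stages) {
    run_stage("hgt", function() {
      tree <- ape::read.tree(cfg$tree_nwk)
      kg_df <- read_tsv_file(cfg$kingdoms_tsv)
      kingdoms <- stats::setNames(kg_df$kingdom, kg_df$gene_id)
      calls <- detect_nested_foreign(tree, kingdoms,
                                     support_min = cfg$support)
      write_tsv_file(calls, out_path("hgt_calls.tsv"))
      ## an empty screen is a result, not a failure
      list(n = max(nrow(calls), 1L), out = out_path("hgt_calls.tsv"))
    })
  }
  if ("te" %in% stages) {
    run_stage("te", function() {
      te <- read_te_gff(cfg$te_gff)
      gmods <- read_gff_genes(cfg$genes_gff)
      genes <- unique(gmods[, c("gene_id", "contig_id", "strand",
                                "start", "end")])
      contigs_df <- read_tsv_file(cfg$contigs_tsv)
      contigs <- stats::setNames(contigs_df$length, contigs_df$contig_id)
      ort <- ort_table(genes, te, contigs, flank_bp = cfg$flank)
      write_tsv_file(ort, out_path("ort.tsv"))
      ltr <- te[!is.na(te$identity), , drop = FALSE]
      if (nrow(ltr) > 0L) {
        times <- ltr_insertion_time(ltr$identity, mu = cfg$mu)
        tdf <- data.frame(contig_id = ltr$contig_id, start = ltr$start,
                          end = ltr$end, te_class = ltr$te_class,
                          identity = ltr$identity, time_mya = times,
                          stringsAsFactors = FALSE)
        write_tsv_file(tdf, out_path("ltr_insertion_times.tsv"))
        write_tsv_file(insertion_time_histogram(times),
                       out_path("ltr_time_histogram.tsv"))
      }
      list(n = nrow(ort), out = out_path("ort.tsv"))
    })
  }

  rep_df <- do.call(rbind, c(unname(report), list(make.row.names = FALSE)))
  write_tsv_file(rep_df, file.path(cfg$outdir, "run_report.tsv"))
  echo <- cfg[c("e_value", "rpkm_threshold", "fdr", "fc", "ks_cutoff",
                "support", "flank", "mu", "alpha", "seed")]
  writeLines(
    yaml::as.yaml(cfg[!vapply(cfg, is.null, logical(1L))]),
    file.path(cfg$outdir, "run_config.yaml")
  )
  attr(rep_df, "config") <- cfg
  attr(rep_df, "parameters") <- echo
  rep_df
}
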