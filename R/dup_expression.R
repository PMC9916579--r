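## RPKM, duplicate-pair differential expression per tissue, and duplicate
## fate classification (SNFD / AED / NDD), plus the cross-species fate
## conservation matrix.
##
## The per-tissue test statistic is the mean per-library
## log2((RPKM_a + 1)/(RPKM_b + 1)) over the tissue's replicate libraries.
## By default the replicate variance is moderated across all (pair, tissue)
## tests with an empirical-Bayes prior (limma::squeezeVar), which plays the
## role the dispersion-sharing step plays in count-based DE tools: with the
## 2-3 replicates typical of public tissue panels, a per-test variance
## estimate alone has so few degrees of freedom that real 8-fold effects
## cannot reach a BH-adjusted 5% FDR. Verdicts additionally require the
## fold-change gate |mean log2 ratio| >= log2(fc_cutoff).

FATE_LEVELS <- c("SNFD", "AED", "NDD")

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = count * 1e9 / (gene_length_nt * total_mapped_reads)`.
#'
#' @param count Read count(s), non-negative.
#' @param gene_length_nt Gene length(s) in nucleotides, > 0.
#' @param total_mapped_reads Library size(s), > 0.
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(count, gene_length_nt, total_mapped_reads) {
  if (any(gene_length_nt <= 0)) stop("gene_length_nt must be > 0")
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0")
  count * 1e9 / (gene_length_nt * total_mapped_reads)
}

#' RPKM matrix from a count matrix
#'
#' @param counts Integer matrix, genes x libraries, with dimnames.
#' @param gene_lengths Named vector of gene lengths (nt) covering all rows.
#' @param library_sizes Named vector of total mapped reads covering all
#'   columns.
#' @return Numeric matrix of RPKM values with the same dimnames.
#' @export
rpkm_matrix <- function(counts, gene_lengths, library_sizes) {
  if (!all(rownames(counts) %in% names(gene_lengths))) {
    stop("gene_lengths must cover every row of counts")
  }
  if (!all(colnames(counts) %in% names(library_sizes))) {
    stop("library_sizes must cover every column of counts")
  }
  len <- gene_lengths[rownames(counts)]
  lib <- library_sizes[colnames(counts)]
  sweep(sweep(counts * 1e9, 1L, len, "/"), 2L, lib, "/")
}

#' Fraction of genes expressed above an RPKM threshold
#'
#' Strict inequality: a gene counts as expressed only when its RPKM
#' exceeds the threshold.
#'
#' @param rpkm_values Numeric vector (one value per gene, e.g. the
#'   per-tissue mean RPKM).
#' @param threshold Expression threshold (default 5).
#' @return Fraction in `[0, 1]`.
#' @export
expressed_ratio <- function(rpkm_values, threshold = 5) {
  if (length(rpkm_values) == 0L) stop("need at least one gene")
  mean(rpkm_values > threshold)
}

#' Per-tissue differential-expression tests for duplicate pairs
#'
#' For every pair and tissue, computes per-library
#' `log2((RPKM_a + 1)/(RPKM_b + 1))` and tests whether its mean differs
#' from zero. With two or more replicates a one-sample t-test is used,
#' moderated across all tests by default (see [limma::squeezeVar()]);
#' p-values are BH-adjusted across every (pair, tissue) test in the run. A
#' verdict (`a_higher`/`b_higher`) requires adjusted p below `fdr_alpha`
#' and `|mean log2 ratio| >= log2(fc_cutoff)`. With a single replicate only
#' the fold-change gate applies.
#'
#' Pairs in which neither gene exceeds `rpkm_threshold` in any library are
#' excluded from testing (their rows carry verdict `NA`); a fate cannot be
#' meaningfully assigned to fully silent pairs.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param counts Count matrix, genes x libraries.
#' @param lib_meta data.frame with columns `library`, `tissue`,
#'   `replicate`, `total_mapped_reads`; every column of `counts` must
#'   appear.
#' @param gene_lengths Named vector of gene lengths (nt).
#' @param fdr_alpha FDR level on BH-adjusted p-values (default 0.05).
#' @param fc_cutoff Fold-change gate (default 2).
#' @param rpkm_threshold Expression threshold for the silent-pair exclusion
#'   (default 5).
#' @param moderated Moderate variances across tests (default `TRUE`)?
#' @return data.frame with one row per (pair, tissue): `gene_a`, `gene_b`,
#'   `tissue`, `n_libs`, `mean_log2_ratio`, `p`, `adj_p`, `verdict`
#'   (`a_higher`, `b_higher`, `none`, or `NA` for excluded silent pairs).
#' @export
test_duplicate_pairs <- function(pairs, counts, lib_meta, gene_lengths,
                                 fdr_alpha = 0.05, fc_cutoff = 2,
                                 rpkm_threshold = 5, moderated = TRUE) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  req <- c("library", "tissue", "replicate", "total_mapped_reads")
  stopifnot(all(req %in% names(lib_meta)))
  if (!all(colnames(counts) %in% lib_meta$library)) {
    stop("every count column needs a row in lib_meta")
  }
  missing_genes <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)),
                           rownames(counts))
  if (length(missing_genes) > 0L) {
    stop("pair genes absent from counts: ",
         paste(utils::head(missing_genes, 3L), collapse = ", "))
  }
  lib_sizes <- stats::setNames(lib_meta$total_mapped_reads, lib_meta$library)
  rk <- rpkm_matrix(counts, gene_lengths, lib_sizes)
  tissues <- unique(lib_meta$tissue[match(colnames(counts), lib_meta$library)])
  tissue_of <- stats::setNames(lib_meta$tissue, lib_meta$library)

  silent <- rep(FALSE, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    silent[i] <- all(rk[pairs$gene_a[i], ] <= rpkm_threshold) &&
      all(rk[pairs$gene_b[i], ] <= rpkm_threshold)
  }
  if (any(silent)) {
    message(sum(silent), " pair(s) unexpressed (RPKM <= ", rpkm_threshold,
            " everywhere); excluded from fate testing")
  }

  grid <- expand.grid(pair = seq_len(nrow(pairs)), tissue = tissues,
                      stringsAsFactors = FALSE)
  m <- numeric(nrow(grid)); s2 <- rep(NA_real_, nrow(grid))
  nl <- integer(nrow(grid))
  la <- log2(rk[pairs$gene_a, , drop = FALSE] + 1)
  lb <- log2(rk[pairs$gene_b, , drop = FALSE] + 1)
  ratio <- la - lb
  for (k in seq_len(nrow(grid))) {
    cols <- colnames(counts)[tissue_of[colnames(counts)] == grid$tissue[k]]
    r <- ratio[grid$pair[k], cols]
    nl[k] <- length(r)
    m[k] <- mean(r)
    if (nl[k] >= 2L) s2[k] <- stats::var(r)
  }

  p <- rep(NA_real_, nrow(grid))
  testable <- nl >= 2L & !silent[grid$pair]
  if (any(testable)) {
    p[testable] <- log_ratio_pvalues(m[testable], s2[testable],
                                     nl[testable], moderated)
  }
  adj <- rep(NA_real_, nrow(grid))
  adj[testable] <- stats::p.adjust(p[testable], method = "BH")

  fc_gate <- abs(m) >= log2(fc_cutoff)
  verdict <- rep("none", nrow(grid))
  sig <- ifelse(nl >= 2L, !is.na(adj) & adj < fdr_alpha & fc_gate, fc_gate)
  verdict[sig & m > 0] <- "a_higher"
  verdict[sig & m < 0] <- "b_higher"
  verdict[silent[grid$pair]] <- NA_character_

  out <- data.frame(
    gene_a = pairs$gene_a[grid$pair],
    gene_b = pairs$gene_b[grid$pair],
    tissue = grid$tissue,
    n_libs = nl,
    mean_log2_ratio = m,
    p = p,
    adj_p = adj,
    verdict = verdict,
    stringsAsFactors = FALSE
  )
  out[order(match(out$gene_a, pairs$gene_a), out$tissue), , drop = FALSE]
}

## One-sample (moderated) t-test p-values for mean log-ratios.
log_ratio_pvalues <- function(m, s2, n, moderated) {
  df <- n - 1L
  if (moderated && length(s2) >= 2L && any(s2 > 0)) {
    sq <- tryCatch(limma::squeezeVar(s2, df), error = function(e) NULL)
    if (!is.null(sq)) {
      se <- sqrt(sq$var.post / n)
      tt <- m / se
      df_tot <- df + sq$df.prior
      pv <- ifelse(is.finite(df_tot),
                   2 * stats::pt(-abs(tt), df_tot),
                   2 * stats::pnorm(-abs(tt)))
      ## zero posterior variance: degenerate, fall back on exact outcome
      pv[!is.finite(tt)] <- ifelse(m[!is.finite(tt)] == 0, 1, 0)
      return(pv)
    }
  }
  se <- sqrt(s2 / n)
  tt <- m / se
  pv <- 2 * stats::pt(-abs(tt), df)
  pv[!is.finite(tt)] <- ifelse(m[!is.finite(tt)] == 0, 1, 0)
  pv
}

#' Classify the fate of one duplicate pair from per-tissue verdicts
#'
#' SNFD (sub-/neo-functionalized) when each gene is significantly higher in
#' at least one tissue; otherwise AED (asymmetrically expressed) when one
#' gene is higher in at least one third of the tissues (ceiling) and its
#' sister is never significantly higher; otherwise NDD (no difference).
#' SNFD is checked first.
#'
#' @param verdicts Character vector over tissues, values in
#'   `a_higher`/`b_higher`/`none`; at least two tissues required.
#' @return `"SNFD"`, `"AED"`, or `"NDD"` (`NA` with a warning when fewer
#'   than two tissues are given).
#' @export
classify_fate <- function(verdicts) {
  verdicts <- verdicts[!is.na(verdicts)]
  t_total <- length(verdicts)
  if (t_total < 2L) {
    warning("fate not assigned: need verdicts from at least two tissues")
    return(NA_character_)
  }
  a <- sum(verdicts == "a_higher")
  b <- sum(verdicts == "b_higher")
  need <- ceiling(t_total / 3)
  if (a >= 1L && b >= 1L) return("SNFD")
  if ((a >= need && b == 0L) || (b >= need && a == 0L)) return("AED")
  "NDD"
}

#' Classify fates for a table of per-tissue tests
#'
#' @param tests Output of [test_duplicate_pairs()].
#' @return data.frame with one row per pair: `gene_a`, `gene_b`,
#'   `n_tissues`, `fate` (`NA` for pairs excluded as unexpressed).
#' @export
classify_fates <- function(tests) {
  key <- paste(tests$gene_a, tests$gene_b, sep = "\r")
  out <- lapply(split(tests, factor(key, levels = unique(key))), function(d) {
    data.frame(
      gene_a = d$gene_a[1L], gene_b = d$gene_b[1L],
      n_tissues = nrow(d),
      fate = if (all(is.na(d$verdict))) NA_character_
             else classify_fate(d$verdict),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res
}

#' Cross-species fate-conservation matrix
#'
#' For each species and orthogroup: `SNFD` when any duplicate pair of that
#' species inside the orthogroup is SNFD; `present-not-SNFD` when the
#' species has genes in the orthogroup but no SNFD pair; `absent`
#' otherwise.
#'
#' @param fates data.frame with columns `gene_a`, `gene_b`, `fate`,
#'   `species_id`.
#' @param orthogroups Long-format orthogroup table (`og_id`, `species_id`,
#'   `gene_id`).
#' @param species_ids Species to include as rows.
#' @return Character matrix, species x orthogroups.
#' @export
fate_conservation_matrix <- function(fates, orthogroups, species_ids) {
  ogs <- sort(unique(orthogroups$og_id))
  mat <- matrix("absent", nrow = length(species_ids), ncol = length(ogs),
                dimnames = list(species_ids, ogs))
  present <- unique(orthogroups[, c("og_id", "species_id")])
  present <- present[present$species_id %in% species_ids, , drop = FALSE]
  mat[cbind(present$species_id, present$og_id)] <- "present-not-SNFD"
  snfd <- fates[!is.na(fates$fate) & fates$fate == "SNFD", , drop = FALSE]
  if (nrow(snfd) > 0L) {
    og_genes <- split(orthogroups$gene_id, orthogroups$og_id)
    for (i in seq_len(nrow(snfd))) {
      sp <- snfd$species_id[i]
      if (!sp %in% species_ids) next
      in_og <- vapply(og_genes, function(g) {
        snfd$gene_a[i] %in% g && snfd$gene_b[i] %in% g
      }, logical(1L))
      mat[sp, names(og_genes)[in_og]] <- "SNFD"
    }
  }
  mat
}
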