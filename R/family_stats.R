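## Copy-number statistics across lineages: per-genome means, coefficient of
## variation, and per-orthogroup Wilcoxon tests of copy-number divergence
## between flowering and non-flowering plants.

#' Orthogroup-by-species copy-number matrix
#'
#' @param orthogroups Long-format data.frame with columns `og_id` and
#'   `species_id` (one row per member gene; see [read_orthogroups()]).
#' @param species_ids Character vector of all species to include as columns;
#'   species with no members get an all-zero column.
#' @return Integer matrix (orthogroups x species). Row sums equal orthogroup
#'   sizes.
#' @export
copy_number_matrix <- function(orthogroups, species_ids) {
  stopifnot(all(c("og_id", "species_id") %in% names(orthogroups)))
  if (!all(orthogroups$species_id %in% species_ids)) {
    stop("orthogroup members reference species absent from species_ids")
  }
  tab <- table(
    factor(orthogroups$og_id, levels = sort(unique(orthogroups$og_id))),
    factor(orthogroups$species_id, levels = species_ids)
  )
  mat <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  names(dimnames(mat)) <- NULL
  mat
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean. Returns
#' `NA` when fewer than two values are given or the mean is zero, where the
#' statistic is undefined.
#'
#' @param counts Numeric vector of non-negative values (e.g. family sizes
#'   across species).
#' @return Non-negative real, or `NA_real_`.
#' @export
coefficient_of_variation <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L || mean(counts) == 0) return(NA_real_)
  stats::sd(counts) / mean(counts)
}

#' Mean gene count per genome
#'
#' @param total_genes Total number of genes over all genomes.
#' @param n_genomes Number of genomes (>= 1).
#' @return `total_genes / n_genomes`, rounded to two decimals.
#' @export
mean_per_genome <- function(total_genes, n_genomes) {
  stopifnot(n_genomes >= 1)
  round(total_genes / n_genomes, 2)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses the exact null distribution when the pooled sample size is at most
#' 12 and the pooled values carry no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y Non-empty numeric vectors (the two groups).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  pooled <- c(x, y)
  exact <- (length(pooled) <= 12L) && !anyDuplicated(pooled)
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  p <- unname(res$p.value)
  ## fully tied pooled sample: no evidence of a shift in either direction
  if (is.nan(p)) p <- 1
  min(p, 1)
}

#' Flag orthogroups with divergent copy number between groups
#'
#' Runs a per-orthogroup two-sided Wilcoxon rank-sum test of flowering
#' versus non-flowering copy counts (zero counts included), adjusts across
#' orthogroups with Benjamini-Hochberg, and flags orthogroups whose
#' adjusted p-value falls below `alpha`. Direction compares group medians,
#' falling back to means when the medians tie.
#'
#' @param cn_matrix Copy-number matrix from [copy_number_matrix()]; columns
#'   are species.
#' @param species_meta data.frame from [read_species_table()] covering all
#'   columns of `cn_matrix`; both groups need at least two species.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return data.frame with columns `og_id`, `p_value`, `fdr_adjusted_p`,
#'   `direction` (`flowering-higher`, `non-flowering-higher`, `none`), and
#'   `flagged`.
#' @export
flag_divergent_orthogroups <- function(cn_matrix, species_meta, alpha = 0.05) {
  grp <- species_meta$group[match(colnames(cn_matrix), species_meta$species_id)]
  if (anyNA(grp)) {
    stop("cn_matrix columns missing from species_meta: ",
         paste(colnames(cn_matrix)[is.na(grp)], collapse = ", "))
  }
  fl <- grp == "flowering"
  if (sum(fl) < 2L || sum(!fl) < 2L) {
    stop("need at least two species in each of the flowering and non-flowering groups")
  }
  p <- apply(cn_matrix, 1L, function(row) {
    wilcoxon_rank_sum(row[fl], row[!fl])
  })
  direction <- apply(cn_matrix, 1L, function(row) {
    a <- stats::median(row[fl]); b <- stats::median(row[!fl])
    if (a == b) { a <- mean(row[fl]); b <- mean(row[!fl]) }
    if (a > b) "flowering-higher" else if (a < b) "non-flowering-higher" else "none"
  })
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(
    og_id = rownames(cn_matrix),
    p_value = unname(p),
    fdr_adjusted_p = unname(adj),
    direction = unname(direction),
    flagged = unname(adj < alpha),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
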