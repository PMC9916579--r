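## Transposable-element context of genes: occurrence rate of TEs (ORT) in
## gene bodies and 5-kb flanks, LTR insertion-time dating from terminal
## repeat identity, and ORT-vs-expression correlation by duplicate fate.

TE_CLASSES <- c("Gypsy", "Copia", "other_LTR", "hAT", "Mutator", "CACTA",
                "other_TIR", "Helitron", "other")
LTR_CLASSES <- c("Gypsy", "Copia", "other_LTR")

#' Merge intervals into maximal disjoint runs
#'
#' Computes the union of 0-based half-open intervals (per contig when a
#' `contig_id` column is present) via [IRanges::reduce()].
#'
#' @param intervals data.frame with columns `start`, `end` (0-based
#'   half-open) and optionally `contig_id`.
#' @return data.frame of disjoint sorted intervals with the same columns.
#' @export
merge_intervals <- function(intervals) {
  stopifnot(all(c("start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) return(intervals[, intersect(c("contig_id", "start", "end"), names(intervals)), drop = FALSE])
  if (any(intervals$start >= intervals$end)) {
    stop("intervals must be non-empty half-open spans")
  }
  contig <- if ("contig_id" %in% names(intervals)) {
    as.character(intervals$contig_id)
  } else {
    rep(".", nrow(intervals))
  }
  out <- lapply(split(seq_len(nrow(intervals)), contig), function(i) {
    ir <- IRanges::reduce(IRanges::IRanges(intervals$start[i] + 1L,
                                           intervals$end[i]))
    data.frame(contig_id = contig[i][1L],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (!"contig_id" %in% names(intervals)) res$contig_id <- NULL
  res
}

#' Total length of an interval union
#'
#' @param intervals data.frame as for [merge_intervals()].
#' @return Measure of the union (sum of merged interval lengths).
#' @export
interval_union_length <- function(intervals) {
  m <- merge_intervals(intervals)
  if (nrow(m) == 0L) return(0L)
  sum(m$end - m$start)
}

#' Strand-aware flanking regions of a gene
#'
#' Upstream is the 5' side of the gene's strand. Flanks are truncated (not
#' shifted) at contig bounds, so a gene at a contig edge can have an empty
#' flank.
#'
#' @param gene_start,gene_end Gene span, 0-based half-open, within the
#'   contig.
#' @param strand `"+"` or `"-"`.
#' @param contig_length Contig length in bp.
#' @param flank_bp Flank width (default 5000).
#' @return data.frame with rows `upstream_5kb` and `downstream_5kb`
#'   (columns `region`, `start`, `end`); zero-length rows mark missing
#'   flanks.
#' @export
flank_regions <- function(gene_start, gene_end, strand, contig_length,
                          flank_bp = 5000) {
  stopifnot(flank_bp > 0, gene_start >= 0, gene_end <= contig_length,
            gene_start < gene_end, strand %in% c("+", "-"))
  left <- c(max(0, gene_start - flank_bp), gene_start)
  right <- c(gene_end, min(contig_length, gene_end + flank_bp))
  up <- if (strand == "+") left else right
  down <- if (strand == "+") right else left
  data.frame(
    region = c("upstream_5kb", "downstream_5kb"),
    start = c(up[1L], down[1L]),
    end = c(up[2L], down[2L]),
    stringsAsFactors = FALSE
  )
}

#' Occurrence rate of TEs in a region
#'
#' `ORT = length(union of TE intervals intersected with the region) /
#' length(region)`. The region may consist of several intervals (their
#' union is used). An empty region yields `NA` with a message, not 0.
#'
#' @param region data.frame of region interval(s) with `start`, `end` and
#'   optionally `contig_id`.
#' @param te_intervals data.frame of TE intervals with `start`, `end` and
#'   optionally `contig_id` (matched against the region's contig when both
#'   carry one).
#' @return ORT in `[0, 1]`, or `NA_real_` for an empty region.
#' @export
occurrence_rate <- function(region, te_intervals) {
  region <- region[region$end > region$start, , drop = FALSE]
  if (nrow(region) == 0L) {
    message("empty region: occurrence rate undefined")
    return(NA_real_)
  }
  both_contigs <- "contig_id" %in% names(region) &&
    "contig_id" %in% names(te_intervals)
  rlen <- interval_union_length(region)
  if (nrow(te_intervals) == 0L) return(0)
  rmerged <- merge_intervals(region)
  tmerged <- merge_intervals(te_intervals)
  contigs <- if (both_contigs) unique(as.character(rmerged$contig_id)) else "."
  total_ov <- 0L
  for (cg in contigs) {
    r <- if (both_contigs) rmerged[rmerged$contig_id == cg, ] else rmerged
    te <- if (both_contigs) tmerged[tmerged$contig_id == cg, ] else tmerged
    if (nrow(te) == 0L) next
    ir <- IRanges::IRanges(r$start + 1L, r$end)
    it <- IRanges::IRanges(te$start + 1L, te$end)
    ov <- IRanges::intersect(ir, it)
    total_ov <- total_ov + sum(IRanges::width(ov))
  }
  total_ov / rlen
}

#' LTR insertion time from terminal-repeat identity
#'
#' `T = K / (2 mu) = (1 - identity) / (2 mu)` years, reported in million
#' years. `identity` is the fraction of identical sites between the two
#' terminal repeats of an intact LTR element; `mu` is the per-site
#' substitution rate per year (default `1e-8`).
#'
#' @param identity Numeric in `[0, 1]` (vectorized).
#' @param mu Substitution rate, > 0.
#' @return Insertion time(s) in million years.
#' @export
ltr_insertion_time <- function(identity, mu = 1e-8) {
  if (any(is.na(identity)) || any(identity < 0) || any(identity > 1)) {
    stop("identity must lie in [0, 1]")
  }
  if (mu <= 0) stop("mu must be > 0")
  (1 - identity) / (2 * mu) / 1e6
}

#' Histogram of insertion times
#'
#' @param times_my Insertion times in million years.
#' @param bin_width Bin width in million years (default 0.05).
#' @return data.frame with `bin_start`, `bin_mid`, `count`; the attribute
#'   `"mode"` holds the midpoint of the most populated bin (smallest on
#'   ties).
#' @export
insertion_time_histogram <- function(times_my, bin_width = 0.05) {
  stopifnot(bin_width > 0, all(times_my >= 0))
  bin <- floor(times_my / bin_width)
  tab <- table(bin)
  out <- data.frame(
    bin_start = as.numeric(names(tab)) * bin_width,
    bin_mid = (as.numeric(names(tab)) + 0.5) * bin_width,
    count = as.integer(tab)
  )
  attr(out, "mode") <- out$bin_mid[which.max(out$count)]
  out
}

#' ORT table for genes and their flanks
#'
#' Computes the occurrence rate of TEs in the gene body and the up-/
#' down-stream flanks of every gene.
#'
#' @param genes data.frame with columns `gene_id`, `contig_id`, `strand`,
#'   `start`, `end` (0-based half-open; e.g. from [read_gff_genes()],
#'   uniqued per gene).
#' @param te data.frame of TE intervals (`contig_id`, `start`, `end`).
#' @param contig_lengths Named vector of contig lengths covering all genes.
#' @param flank_bp Flank width (default 5000).
#' @return data.frame with columns `gene_id`, `region` (`genic`,
#'   `upstream_5kb`, `downstream_5kb`), `ort`.
#' @export
ort_table <- function(genes, te, contig_lengths, flank_bp = 5000) {
  stopifnot(all(genes$contig_id %in% names(contig_lengths)))
  te_by_contig <- split(te, as.character(te$contig_id))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    clen <- contig_lengths[[g$contig_id]]
    tec <- te_by_contig[[g$contig_id]]
    if (is.null(tec)) {
      tec <- data.frame(start = integer(), end = integer())
    }
    fl <- flank_regions(g$start, g$end, g$strand, clen, flank_bp)
    regions <- rbind(
      data.frame(region = "genic", start = g$start, end = g$end,
                 stringsAsFactors = FALSE),
      fl
    )
    ort <- vapply(seq_len(nrow(regions)), function(j) {
      suppressMessages(
        occurrence_rate(regions[j, c("start", "end")],
                        tec[, c("start", "end")])
      )
    }, numeric(1L))
    data.frame(gene_id = g$gene_id, region = regions$region, ort = ort,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Correlation between TE occurrence and expression, by duplicate fate
#'
#' Squared Pearson correlation between ORT and RPKM over the genes of each
#' fate class that pass the expression filter (`RPKM > rpkm_threshold`) and
#' have an ORT value for the requested region. Classes with fewer than
#' three qualifying genes, or with zero variance in either variable, give
#' `NA`.
#'
#' @param ort_records data.frame with columns `gene_id`, `region`, `ort`.
#' @param rpkm_values Named vector of per-gene RPKM in the tissue of
#'   interest.
#' @param fate_labels Named character vector mapping genes to fate classes
#'   (`SNFD`/`AED`/`NDD`).
#' @param region Region to correlate (default `"upstream_5kb"`).
#' @param rpkm_threshold Expression filter (default 5, strict).
#' @return data.frame with columns `fate`, `n`, `r_squared`.
#' @export
ort_expression_correlation <- function(ort_records, rpkm_values, fate_labels,
                                       region = "upstream_5kb",
                                       rpkm_threshold = 5) {
  rec <- ort_records[ort_records$region == region & !is.na(ort_records$ort), ]
  out <- lapply(FATE_LEVELS, function(f) {
    genes <- names(fate_labels)[fate_labels == f]
    genes <- intersect(genes, rec$gene_id)
    genes <- genes[!is.na(rpkm_values[genes]) &
                     rpkm_values[genes] > rpkm_threshold]
    r2 <- NA_real_
    if (length(genes) >= 3L) {
      x <- rec$ort[match(genes, rec$gene_id)]
      y <- unname(rpkm_values[genes])
      if (stats::sd(x) > 0 && stats::sd(y) > 0) {
        r2 <- stats::cor(x, y, method = "pearson")^2
      }
    }
    data.frame(fate = f, n = length(genes), r_squared = r2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Map TE annotation terms to the fixed class vocabulary
#'
#' Accepts Sequence Ontology feature types and `Classification=` strings
#' as emitted by common TE annotation pipelines and maps them onto
#' `r paste(TE_CLASSES, collapse = ", ")`. Unknown terms map to `other`.
#'
#' @param terms Character vector of SO terms or classification strings.
#' @return Character vector of class labels.
#' @export
te_class_map <- function(terms) {
  lut <- c(
    "Gypsy_LTR_retrotransposon" = "Gypsy", "LTR/Gypsy" = "Gypsy",
    "Copia_LTR_retrotransposon" = "Copia", "LTR/Copia" = "Copia",
    "LTR_retrotransposon" = "other_LTR", "LTR/unknown" = "other_LTR",
    "long_terminal_repeat" = "other_LTR",
    "hAT_TIR_transposon" = "hAT", "DNA/DTA" = "hAT",
    "Mutator_TIR_transposon" = "Mutator", "DNA/DTM" = "Mutator",
    "CACTA_TIR_transposon" = "CACTA", "DNA/DTC" = "CACTA",
    "PIF_Harbinger_TIR_transposon" = "other_TIR", "DNA/DTH" = "other_TIR",
    "Tc1_Mariner_TIR_transposon" = "other_TIR", "DNA/DTT" = "other_TIR",
    "helitron" = "Helitron", "Helitron" = "Helitron",
    "DNA/Helitron" = "Helitron"
  )
  out <- unname(lut[terms])
  out[is.na(out)] <- "other"
  out
}

#' Read a TE annotation GFF3
#'
#' Reads an EDTA-style TE GFF3: the feature type (or `Classification=`
#' attribute, when present) is mapped onto the fixed class vocabulary, and
#' the `ltr_identity=` attribute is kept for LTR classes.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open), `te_class`, `identity` (`NA` for non-LTR classes or when
#'   absent).
#' @export
read_te_gff <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  term <- if ("Classification" %in% names(md)) {
    as.character(md$Classification)
  } else {
    as.character(gr$type)
  }
  cls <- te_class_map(term)
  ## fall back to the feature type where the classification did not map
  if ("Classification" %in% names(md)) {
    alt <- te_class_map(as.character(gr$type))
    cls[cls == "other" & alt != "other"] <- alt[cls == "other" & alt != "other"]
  }
  ident <- if ("ltr_identity" %in% names(md)) {
    suppressWarnings(as.numeric(as.character(md$ltr_identity)))
  } else {
    NA_real_
  }
  ident[!cls %in% LTR_CLASSES] <- NA_real_
  data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    te_class = cls,
    identity = ident,
    stringsAsFactors = FALSE
  )
}
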