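## Readers/writers for the external formats the pipeline consumes, plus
## annotation normalization (longest isoform per gene).
##
## Internal coordinate convention: 0-based half-open everywhere. GFF3 and
## HMMER envelope coordinates (1-based inclusive) are converted on ingest.

#' Lineage categories and their flowering/non-flowering group
#'
#' The 22 lineage categories used to stratify species: 11 non-flowering
#' (Rhodophyta through Gymnospermae) and 11 flowering (basal Angiosperms
#' through Malvids). The category fully determines the group.
#'
#' @return A data.frame with columns `category` and `group`
#'   (`"flowering"` or `"non-flowering"`), 22 rows.
#' @export
lineage_categories <- function() {
  data.frame(
    category = c(
      "Rhodophyta", "Prasinodermophyta", "Chlorophyta", "Klebsormidiophyceae",
      "Charophyceae", "Zygnematophyceae", "Marchantiophyta", "Bryophyta",
      "Anthocerotales", "Lycopodiophyta", "Gymnospermae",
      "basal Angiosperms", "Magnoliidae", "Monocotyledoneae",
      "Early-diverging eudicotyledons", "Santalales", "Caryophyllales",
      "Asterids", "Saxifragales", "Vitales", "Fabids", "Malvids"
    ),
    group = rep(c("non-flowering", "flowering"), each = 11L),
    stringsAsFactors = FALSE
  )
}

#' Read a species metadata table
#'
#' TSV with columns `species_id` and `category` (optionally `genome_size`).
#' The category must be one of the 22 known lineage categories; the
#' flowering/non-flowering group is derived from it.
#'
#' @param path Path to a TSV file with a header line.
#' @return data.frame with columns `species_id`, `category`, `group`, and
#'   `genome_size` (NA when absent from the file).
#' @export
read_species_table <- function(path) {
  tab <- read_tsv_file(path)
  req <- c("species_id", "category")
  if (!all(req %in% names(tab))) {
    stop("species table must have columns: ", paste(req, collapse = ", "))
  }
  cats <- lineage_categories()
  bad <- which(!tab$category %in% cats$category)
  if (length(bad) > 0L) {
    stop(sprintf(
      "unknown lineage category '%s' for species '%s' (row %d)",
      tab$category[bad[1L]], tab$species_id[bad[1L]], bad[1L]
    ))
  }
  if (anyDuplicated(tab$species_id)) {
    stop("duplicated species_id in species table: ",
         tab$species_id[duplicated(tab$species_id)][1L])
  }
  data.frame(
    species_id = as.character(tab$species_id),
    category = as.character(tab$category),
    group = cats$group[match(tab$category, cats$category)],
    genome_size = if ("genome_size" %in% names(tab)) {
      as.numeric(tab$genome_size)
    } else {
      NA_real_
    },
    stringsAsFactors = FALSE
  )
}

#' Select the longest isoform per gene
#'
#' Given gene models (one row per transcript), returns the representative
#' transcript of each gene: the one with maximal length, ties broken by
#' lexicographically smaller transcript id.
#'
#' @param gene_models data.frame with columns `gene_id`, `transcript_id`,
#'   and `length` (nt, > 0).
#' @return Named character vector mapping `gene_id` to `transcript_id`.
#' @export
select_longest_isoform <- function(gene_models) {
  req <- c("gene_id", "transcript_id", "length")
  if (!all(req %in% names(gene_models))) {
    stop("gene_models must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(gene_models) == 0L) {
    stop("no transcripts given: every gene needs at least one transcript")
  }
  len <- as.numeric(gene_models$length)
  if (anyNA(len) || any(len <= 0)) {
    stop("every transcript length must be a positive number")
  }
  ord <- order(gene_models$gene_id, -len, gene_models$transcript_id,
               method = "radix")
  first <- !duplicated(gene_models$gene_id[ord])
  sel <- gene_models[ord, ][first, ]
  stats::setNames(as.character(sel$transcript_id), as.character(sel$gene_id))
}

#' Read a domain-hit table
#'
#' Supports two dialects:
#' \describe{
#'   \item{`domtblout`}{HMMER `hmmsearch --domtblout` output
#'     (whitespace-delimited, `#` comment lines). The per-domain
#'     independent E-value (column 13), bit score (column 14), and envelope
#'     coordinates (columns 20-21, 1-based inclusive) are used.}
#'   \item{`simple_tsv`}{A TSV with header
#'     `protein_id, domain_name, e_value, env_start, env_end[, score]` where
#'     coordinates are already 0-based half-open. This is the format
#'     [write_domain_hits()] emits.}
#' }
#' Envelope coordinates are returned 0-based half-open in both cases; rows
#' keep file order.
#'
#' @param path File path.
#' @param dialect `"domtblout"` or `"simple_tsv"`.
#' @return data.frame with columns `protein_id`, `domain_name`, `e_value`,
#'   `env_start`, `env_end`, `score`.
#' @export
read_domain_hits <- function(path, dialect = c("domtblout", "simple_tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "domtblout") {
    lines <- readLines(path)
    keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
    if (length(keep) == 0L) return(empty_domain_hits())
    rows <- lapply(keep, function(i) {
      f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
      if (length(f) < 21L) {
        stop(sprintf("malformed domtblout line %d: %d fields (need >= 21)",
                     i, length(f)))
      }
      ev <- suppressWarnings(as.numeric(f[13L]))
      sc <- suppressWarnings(as.numeric(f[14L]))
      a <- suppressWarnings(as.integer(f[20L]))
      b <- suppressWarnings(as.integer(f[21L]))
      if (anyNA(c(ev, sc, a, b))) {
        stop(sprintf("malformed domtblout line %d: non-numeric field", i))
      }
      data.frame(protein_id = f[1L], domain_name = f[4L], e_value = ev,
                 env_start = a - 1L, env_end = b, score = sc,
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, rows)
  } else {
    tab <- read_tsv_file(path)
    req <- c("protein_id", "domain_name", "e_value", "env_start", "env_end")
    if (!all(req %in% names(tab))) {
      stop("simple_tsv domain hits need columns: ", paste(req, collapse = ", "))
    }
    if (nrow(tab) == 0L) return(empty_domain_hits())
    hits <- data.frame(
      protein_id = as.character(tab$protein_id),
      domain_name = as.character(tab$domain_name),
      e_value = as.numeric(tab$e_value),
      env_start = as.integer(tab$env_start),
      env_end = as.integer(tab$env_end),
      score = if ("score" %in% names(tab)) as.numeric(tab$score) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  validate_domain_hits(hits)
  hits
}

#' Write domain hits in the simple TSV dialect
#'
#' @param hits data.frame as returned by [read_domain_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  validate_domain_hits(hits)
  write_tsv_file(hits, path)
}

empty_domain_hits <- function() {
  data.frame(protein_id = character(), domain_name = character(),
             e_value = numeric(), env_start = integer(), env_end = integer(),
             score = numeric(), stringsAsFactors = FALSE)
}

validate_domain_hits <- function(hits) {
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(!is.finite(hits$e_value)) || any(hits$e_value <= 0)) {
    stop("domain hit e_value must be a positive number")
  }
  if (any(hits$env_start >= hits$env_end)) {
    stop("domain hit envelope must be a non-empty half-open interval")
  }
  invisible(hits)
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' `coords_to_zero_based()` maps a 1-based inclusive interval (GFF3/HMMER
#' style) to the internal 0-based half-open convention;
#' `coords_to_one_based()` is its inverse.
#'
#' @param start,end Interval bounds (vectors allowed).
#' @return A list with components `start` and `end`.
#' @export
coords_to_zero_based <- function(start, end) {
  list(start = start - 1L, end = end)
}

#' @rdname coords_to_zero_based
#' @export
coords_to_one_based <- function(start, end) {
  list(start = start + 1L, end = end)
}

#' Read gene models from a GFF3 file
#'
#' Extracts genes and their transcripts (`mRNA`/`transcript` features with a
#' `Parent` attribute). Transcript length is the summed exon length when
#' exons are annotated, otherwise the transcript span. Genes without
#' annotated transcripts act as their own single transcript. Coordinates are
#' converted to 0-based half-open.
#'
#' @param path GFF3 file path.
#' @return data.frame with one row per transcript: `gene_id`,
#'   `transcript_id`, `length`, `contig_id`, `strand`, `start`, `end`
#'   (the parent gene span).
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  first_parent <- function(p) {
    vapply(p, function(x) if (length(x) == 0L) NA_character_ else x[[1L]],
           character(1L))
  }
  genes <- gr[type == "gene"]
  txs <- gr[type %in% c("mRNA", "transcript")]
  exons <- gr[type == "exon"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  gene_ids <- as.character(genes$ID)
  gdf <- data.frame(
    gene_id = gene_ids,
    contig_id = as.character(GenomicRanges::seqnames(genes)),
    strand = as.character(GenomicRanges::strand(genes)),
    start = GenomicRanges::start(genes) - 1L,
    end = GenomicRanges::end(genes),
    stringsAsFactors = FALSE
  )
  if (length(txs) > 0L) {
    tx_parent <- first_parent(txs$Parent)
    tx_ids <- as.character(txs$ID)
    tx_len <- GenomicRanges::width(txs)
    if (length(exons) > 0L) {
      ex_parent <- first_parent(exons$Parent)
      ex_sum <- tapply(GenomicRanges::width(exons), ex_parent, sum)
      has_ex <- tx_ids %in% names(ex_sum)
      tx_len[has_ex] <- as.integer(ex_sum[tx_ids[has_ex]])
    }
    tdf <- data.frame(gene_id = tx_parent, transcript_id = tx_ids,
                      length = as.integer(tx_len), stringsAsFactors = FALSE)
    tdf <- tdf[tdf$gene_id %in% gene_ids, , drop = FALSE]
  } else {
    tdf <- data.frame(gene_id = character(), transcript_id = character(),
                      length = integer(), stringsAsFactors = FALSE)
  }
  orphan <- setdiff(gene_ids, tdf$gene_id)
  if (length(orphan) > 0L) {
    g <- gdf[match(orphan, gdf$gene_id), ]
    tdf <- rbind(tdf, data.frame(gene_id = orphan, transcript_id = orphan,
                                 length = g$end - g$start,
                                 stringsAsFactors = FALSE))
  }
  out <- merge(tdf, gdf, by = "gene_id", sort = FALSE)
  out[order(out$gene_id, out$transcript_id), , drop = FALSE]
}

#' Read an orthogroup membership table
#'
#' Reads the OrthoFinder `Orthogroups.tsv` dialect: first column the
#' orthogroup id, one column per species, cells holding comma-separated gene
#' lists (empty cell = species absent).
#'
#' @param path TSV file path.
#' @return Long-format data.frame with columns `og_id`, `species_id`,
#'   `gene_id`.
#' @export
read_orthogroups <- function(path) {
  tab <- read_tsv_file(path)
  if (ncol(tab) < 2L) stop("orthogroup table needs an id column plus species columns")
  og_col <- names(tab)[1L]
  species <- names(tab)[-1L]
  out <- list()
  for (sp in species) {
    cell <- as.character(tab[[sp]])
    genes <- strsplit(cell, ",[[:space:]]*")
    n <- lengths(genes)
    keep <- n > 0L & nzchar(cell) & !is.na(cell)
    if (!any(keep)) next
    out[[sp]] <- data.frame(
      og_id = rep(as.character(tab[[og_col]])[keep], lengths(genes[keep])),
      species_id = sp,
      gene_id = unlist(genes[keep], use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$og_id, res$species_id, res$gene_id), , drop = FALSE]
}

#' Write an orthogroup table in the OrthoFinder dialect
#'
#' @param og Long-format data.frame with `og_id`, `species_id`, `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(og, path) {
  species <- sort(unique(og$species_id))
  ogs <- sort(unique(og$og_id))
  mat <- matrix("", nrow = length(ogs), ncol = length(species),
                dimnames = list(ogs, species))
  key <- split(og$gene_id, list(og$og_id, og$species_id), drop = TRUE)
  for (k in names(key)) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    ## og ids and species ids must not contain '.' for this writer
    mat[parts[1L], parts[2L]] <- paste(sort(key[[k]]), collapse = ", ")
  }
  out <- data.frame(Orthogroup = ogs, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv_file(out, path)
}

#' Read paired coding sequences from FASTA
#'
#' Each pair contributes two records whose headers follow the
#' `pair_id|gene_id` convention.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `pair_id`, `gene_a`, `gene_b`, `cds_a`,
#'   `cds_b`.
#' @export
read_pair_cds <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  nm <- names(seqs)
  parts <- strsplit(nm, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("pair FASTA headers must be 'pair_id|gene_id'")
  }
  pair_id <- vapply(parts, `[`, character(1L), 1L)
  gene_id <- vapply(parts, `[`, character(1L), 2L)
  ids <- unique(pair_id)
  rows <- lapply(ids, function(p) {
    i <- which(pair_id == p)
    if (length(i) != 2L) stop("pair '", p, "' must have exactly two records")
    data.frame(pair_id = p, gene_a = gene_id[i[1L]], gene_b = gene_id[i[2L]],
               cds_a = as.character(seqs[[i[1L]]]),
               cds_b = as.character(seqs[[i[2L]]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Plain TSV helpers: header line, tab-separated, no quoting.

#' Read/write a TSV table with a header line
#'
#' Thin wrappers around [utils::read.delim()] / [utils::write.table()] using
#' the conventions shared by all tables in this package (tab separator,
#' header, no quoting, no row names).
#'
#' @param path File path.
#' @param x data.frame to write.
#' @return `read_tsv_file`: a data.frame; `write_tsv_file`: `path`,
#'   invisibly.
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_file
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
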