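## MYB family membership and 1R-4R subfamily classification from Pfam
## Myb_DNA-binding domain hits.
##
## A protein is a family member when at least one merged domain envelope
## survives the E-value filter; the number of merged envelopes is the repeat
## count, and the repeat count maps onto the four canonical subfamilies
## (1 -> 1R-MYB, 2 -> 2R-MYB, 3 -> 3R-MYB, >= 4 -> 4R-MYB).

MYB_DOMAIN_NAME <- "Myb_DNA-binding"

#' Merge overlapping domain envelopes
#'
#' Two envelopes are treated as the same repeat when their residue overlap
#' exceeds half the shorter envelope; merging is transitive (connected
#' components of the overlap graph). This absorbs split or duplicated HMM
#' envelopes of a single repeat without joining adjacent repeats, which
#' typically abut with little overlap.
#'
#' @param start,end Envelope bounds, 0-based half-open.
#' @param min_overlap Fraction of the shorter envelope that must be covered
#'   for a merge (default 0.5, strict inequality).
#' @return Integer vector of component ids (1-based, in order of first
#'   appearance); `length(unique(.))` is the merged envelope count.
#' @export
merge_hit_envelopes <- function(start, end, min_overlap = 0.5) {
  n <- length(start)
  stopifnot(length(end) == n)
  if (n == 0L) return(integer(0L))
  if (any(start >= end)) stop("envelopes must be non-empty half-open intervals")
  comp <- seq_len(n)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  len <- end - start
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ov <- min(end[i], end[j]) - max(start[i], start[j])
      if (ov > min_overlap * min(len[i], len[j])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}

#' Count MYB repeats in one protein
#'
#' Hits with E-value above the threshold are discarded; surviving envelopes
#' are merged with [merge_hit_envelopes()] and the merged envelopes are
#' counted. An empty input (or one with no surviving hits) gives 0.
#'
#' @param hits data.frame of domain hits for a single protein, with columns
#'   `e_value`, `env_start`, `env_end` (see [read_domain_hits()]).
#' @param e_threshold Inclusion threshold: hits with `e_value > e_threshold`
#'   are dropped (default `1e-5`).
#' @return Integer repeat count (>= 0).
#' @export
count_myb_repeats <- function(hits, e_threshold = 1e-5) {
  stopifnot(e_threshold > 0)
  if (is.null(hits) || nrow(hits) == 0L) return(0L)
  keep <- hits$e_value <= e_threshold
  if (!any(keep)) return(0L)
  comp <- merge_hit_envelopes(hits$env_start[keep], hits$env_end[keep])
  length(unique(comp))
}

#' Map a repeat count to its MYB subfamily
#'
#' 1 -> `1R-MYB`, 2 -> `2R-MYB`, 3 -> `3R-MYB`, and 4 or more -> `4R-MYB`
#' (the "4R-like" bucket). Counts below 1 are not family members and raise
#' an error.
#'
#' @param repeat_count Integer vector of repeat counts (>= 1).
#' @return Character vector of subfamily labels.
#' @export
classify_subfamily <- function(repeat_count) {
  if (any(repeat_count < 1L)) {
    stop("repeat_count must be >= 1: a protein without a MYB repeat is not a family member")
  }
  ifelse(repeat_count >= 4L, "4R-MYB", paste0(repeat_count, "R-MYB"))
}

#' Build the MYB family table across species
#'
#' Filters hits to the canonical domain name, applies the E-value threshold,
#' merges envelopes per protein, and returns one row per protein with at
#' least one surviving repeat. Hits referencing proteins absent from
#' `protein_species` are skipped with a single warning reporting the count.
#'
#' @param hits data.frame of domain hits (all species pooled), columns as in
#'   [read_domain_hits()].
#' @param protein_species data.frame mapping `protein_id` to `species_id`
#'   (the longest-isoform protein set).
#' @param e_threshold E-value inclusion threshold (default `1e-5`).
#' @param domain_name Domain used for family membership (default
#'   `"Myb_DNA-binding"`).
#' @return data.frame with columns `protein_id`, `species_id`,
#'   `repeat_count`, `subfamily`, ordered by (species, protein id).
#' @export
build_family_table <- function(hits, protein_species, e_threshold = 1e-5,
                               domain_name = MYB_DOMAIN_NAME) {
  stopifnot(all(c("protein_id", "species_id") %in% names(protein_species)))
  empty <- data.frame(protein_id = character(), species_id = character(),
                      repeat_count = integer(), subfamily = character(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits <- hits[hits$domain_name == domain_name, , drop = FALSE]
  known <- hits$protein_id %in% protein_species$protein_id
  if (any(!known)) {
    warning(sum(!known), " hit(s) reference proteins absent from the ",
            "longest-isoform set; skipped")
    hits <- hits[known, , drop = FALSE]
  }
  if (nrow(hits) == 0L) return(empty)
  counts <- vapply(
    split(hits, hits$protein_id),
    count_myb_repeats,
    integer(1L),
    e_threshold = e_threshold
  )
  counts <- counts[counts >= 1L]
  if (length(counts) == 0L) return(empty)
  out <- data.frame(
    protein_id = names(counts),
    species_id = protein_species$species_id[
      match(names(counts), protein_species$protein_id)],
    repeat_count = as.integer(counts),
    subfamily = classify_subfamily(as.integer(counts)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$species_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally subfamily membership
#'
#' @param family_table Output of [build_family_table()].
#' @param by Optional grouping column of `family_table` (e.g.
#'   `"species_id"`).
#' @return A contingency table of subfamily counts.
#' @export
subfamily_tally <- function(family_table, by = NULL) {
  lv <- c("1R-MYB", "2R-MYB", "3R-MYB", "4R-MYB")
  f <- factor(family_table$subfamily, levels = lv)
  if (is.null(by)) table(subfamily = f)
  else table(group = family_table[[by]], subfamily = f)
}
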