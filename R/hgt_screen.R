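## Screening gene trees for candidate plant <-> fungus/oomycete horizontal
## transfers.
##
## A manual topology inspection is replaced by an explicit double-enclosure
## rule: a small same-kingdom clade is called when both its sister clade
## and the next-outer neighbouring clade consist entirely of the other
## kingdom and both enclosing bipartitions carry bootstrap support at or
## above the threshold. Trees are canonicalized by midpoint rooting so the
## result does not depend on how the input happened to be rooted.

KINGDOM_LEVELS <- c("plant", "fungus_oomycete")

#' Flag orthogroups mixing plant and fungus/oomycete genes
#'
#' @param orthogroups Long-format data.frame with columns `og_id` and
#'   `kingdom` (one row per member gene); every member must carry a
#'   kingdom label.
#' @return Character vector of flagged orthogroup ids (those containing at
#'   least one member of each kingdom).
#' @export
flag_mixed_orthogroups <- function(orthogroups) {
  stopifnot(all(c("og_id", "kingdom") %in% names(orthogroups)))
  if (nrow(orthogroups) == 0L) stop("empty orthogroup table")
  if (anyNA(orthogroups$kingdom) ||
      !all(orthogroups$kingdom %in% KINGDOM_LEVELS)) {
    stop("every member needs a kingdom label in {",
         paste(KINGDOM_LEVELS, collapse = ", "), "}")
  }
  has <- table(orthogroups$og_id, orthogroups$kingdom)
  ids <- rownames(has)[rowSums(has > 0) == 2L]
  sort(ids)
}

#' Detect foreign clades nested inside the other kingdom
#'
#' Identifies maximal same-kingdom clades C such that (i) the sister clade
#' of C is entirely the other kingdom, (ii) the next-outer neighbouring
#' clade is also entirely the other kingdom, and (iii) both enclosing
#' bipartitions have support at or above `support_min`. Only
#' minority clades are called (at most `minority_frac` of the tips), so
#' the vertically inherited majority is never reported as transferred.
#' Clades meeting (i) but failing (ii) or the support gate are returned as
#' low-confidence candidates.
#'
#' The tree is unrooted and midpoint-rooted before analysis, which makes
#' the result invariant to the input rooting; support values are carried
#' through rerooting as bipartition (not node) attributes.
#'
#' @param tree An `ape::phylo` gene tree with branch lengths and bootstrap
#'   support (0-100) as internal node labels.
#' @param kingdoms Named character vector mapping every tip label to
#'   `"plant"` or `"fungus_oomycete"`.
#' @param support_min Minimum bootstrap support for the two enclosing
#'   bipartitions (default 70).
#' @param minority_frac Maximum fraction of tips a called clade may contain
#'   (default 0.2).
#' @return data.frame with one row per tip of each candidate clade:
#'   `gene_id`, `clade` (integer id grouping tips called together),
#'   `direction` (`fungi_to_plant` or `plant_to_fungi`), `support`
#'   (minimum over the two enclosing bipartitions), `confidence`
#'   (`"high"` for double enclosure passing the support gate, `"low"`
#'   otherwise).
#' @export
detect_nested_foreign <- function(tree, kingdoms, support_min = 70,
                                  minority_frac = 0.2) {
  stopifnot(inherits(tree, "phylo"))
  stopifnot(support_min >= 0, support_min <= 100)
  ntip <- length(tree$tip.label)
  if (ntip < 4L) stop("need a tree with at least 4 tips")
  if (!all(tree$tip.label %in% names(kingdoms))) {
    stop("unlabeled tip(s): ",
         paste(setdiff(tree$tip.label, names(kingdoms)), collapse = ", "))
  }
  kg <- kingdoms[tree$tip.label]
  if (!all(kg %in% KINGDOM_LEVELS)) {
    stop("kingdom labels must be in {", paste(KINGDOM_LEVELS, collapse = ", "), "}")
  }
  if (length(unique(kg)) < 2L) {
    return(empty_hgt_calls())
  }

  tree <- phangorn::midpoint(ape::unroot(tree), node.labels = "support")
  tree <- stats::reorder(tree, "postorder")
  kg <- kingdoms[tree$tip.label]

  nnode <- tree$Nnode
  nall <- ntip + nnode
  root <- ntip + 1L
  parent <- integer(nall)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  children <- split(tree$edge[, 2L], tree$edge[, 1L])

  ## per-node tip kingdoms: pure kingdom, NA (mixed), or "" (not yet seen);
  ## postorder edge order guarantees a child's subtree is complete when its
  ## edge is reached, so folding edge by edge fills parents correctly
  purek <- character(nall)
  sizes <- integer(nall)
  purek[seq_len(ntip)] <- kg
  sizes[seq_len(ntip)] <- 1L
  for (e in seq_len(nrow(tree$edge))) {
    v <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    sizes[v] <- sizes[v] + sizes[ch]
    purek[v] <- if (!is.na(purek[v]) && purek[v] == "") {
      purek[ch]
    } else if (is.na(purek[v]) || is.na(purek[ch]) || purek[v] != purek[ch]) {
      NA_character_
    } else {
      purek[v]
    }
  }

  node_support <- function(v) {
    if (v <= ntip) return(100)             # trivial single-tip bipartition
    lab <- tree$node.label[v - ntip]
    s <- suppressWarnings(as.numeric(lab))
    if (is.na(s)) 100 else s               # unlabeled split treated as unsupported? no: pass-through
  }

  calls <- list()
  clade_id <- 0L
  cap <- minority_frac * ntip
  for (v in seq_len(nall)) {
    if (v == root) next
    k <- purek[v]
    if (is.na(k) || k == "") next
    p <- parent[v]
    if (p != root && !is.na(purek[p]) && purek[p] == k) next  # not maximal
    if (p == root) {
      ## sister of v is the rest of the tree; v maximal by construction
      sibs <- setdiff(children[[as.character(p)]], v)
      if (length(sibs) == 0L) next
      sis_pure <- all(purek[sibs] == other_kingdom(k), na.rm = FALSE)
      ## no next-outer clade exists at the root
      if (isTRUE(sis_pure) && sizes[v] <= cap) {
        clade_id <- clade_id + 1L
        calls[[length(calls) + 1L]] <- hgt_call_row(
          tree, v, ntip, clade_id, k,
          support = node_support(v), confidence = "low")
      }
      next
    }
    sibs <- setdiff(children[[as.character(p)]], v)
    sis_pure <- length(sibs) > 0L &&
      all(!is.na(purek[sibs]) & purek[sibs] == other_kingdom(k))
    if (!sis_pure) next
    if (sizes[v] > cap) next
    g <- parent[p]
    outer_ok <- FALSE
    sup2 <- NA_real_
    if (g != 0L) {
      outers <- setdiff(children[[as.character(g)]], p)
      outer_ok <- length(outers) > 0L &&
        all(!is.na(purek[outers]) & purek[outers] == other_kingdom(k))
      sup2 <- if (g == root) {
        ## the root split equals the bipartition of the sibling clade
        min(vapply(outers, node_support, numeric(1L)))
      } else {
        node_support(g)
      }
    }
    sup1 <- node_support(p)
    supp <- suppressWarnings(min(sup1, sup2, na.rm = TRUE))
    high <- outer_ok && sup1 >= support_min && sup2 >= support_min
    clade_id <- clade_id + 1L
    calls[[length(calls) + 1L]] <- hgt_call_row(
      tree, v, ntip, clade_id, k,
      support = supp, confidence = if (isTRUE(high)) "high" else "low")
  }
  if (length(calls) == 0L) return(empty_hgt_calls())
  out <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  out[order(out$clade, out$gene_id), , drop = FALSE]
}

other_kingdom <- function(k) {
  if (k == "plant") "fungus_oomycete" else "plant"
}

hgt_call_row <- function(tree, v, ntip, clade_id, clade_kingdom, support,
                         confidence) {
  tips <- if (v <= ntip) {
    tree$tip.label[v]
  } else {
    tree$tip.label[unlist(phangorn::Descendants(tree, v, type = "tips"))]
  }
  data.frame(
    gene_id = tips,
    clade = clade_id,
    direction = if (clade_kingdom == "plant") "fungi_to_plant"
                else "plant_to_fungi",
    support = support,
    confidence = confidence,
    stringsAsFactors = FALSE
  )
}

empty_hgt_calls <- function() {
  data.frame(gene_id = character(), clade = integer(),
             direction = character(), support = numeric(),
             confidence = character(), stringsAsFactors = FALSE)
}

#' Corroborate an HGT candidate with ranked homology hits
#'
#' @param hits data.frame of homolog hits for one gene with a
#'   `subject_kingdom` column; ranked best-first (re-ranked by `bitscore`
#'   when that column is present). Self-species hits are assumed removed
#'   upstream.
#' @param donor_kingdom The putative donor (`"plant"` or
#'   `"fungus_oomycete"`).
#' @param n_top Number of top hits examined (default 10).
#' @param majority Fraction of the top hits that must come from the donor
#'   kingdom, strict inequality (default 0.5).
#' @return `TRUE` when more than `majority` of the top `n_top` hits are
#'   from the donor kingdom; `FALSE` otherwise (including an empty table).
#' @export
tophit_corroborate <- function(hits, donor_kingdom, n_top = 10,
                               majority = 0.5) {
  if (is.null(hits) || nrow(hits) == 0L) return(FALSE)
  stopifnot("subject_kingdom" %in% names(hits))
  if ("bitscore" %in% names(hits)) {
    hits <- hits[order(-hits$bitscore), , drop = FALSE]
  }
  top <- utils::head(hits, n_top)
  mean(top$subject_kingdom == donor_kingdom) > majority
}
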