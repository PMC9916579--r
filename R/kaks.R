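## Nei-Gojobori (1986) Ka/Ks estimation for pre-aligned duplicate coding
## sequence pairs, with Jukes-Cantor multiple-hit correction.
##
## Sites: each codon position contributes (synonymous single-nucleotide
## neighbours / non-stop neighbours) synonymous sites, so S + N = 3 per
## codon. Differences: for each codon pair, every minimal mutational pathway
## (ordering of the differing positions) that avoids stop-codon
## intermediates is enumerated and the synonymous/nonsynonymous step counts
## are averaged with equal weights. Codon pairs whose pathways all pass
## through a stop are skipped. All per-codon quantities are precomputed as
## 64 x 64 lookup tables on first use.

NUCLEOTIDES <- c("A", "C", "G", "T")

.kaks_cache <- new.env(parent = emptyenv())

## codon index: 16*n1 + 4*n2 + n3 + 1 with A,C,G,T = 0..3
codon_strings <- function() {
  idx <- 0:63
  paste0(NUCLEOTIDES[idx %/% 16L + 1L],
         NUCLEOTIDES[(idx %/% 4L) %% 4L + 1L],
         NUCLEOTIDES[idx %% 4L + 1L])
}

ng86_tables <- function() {
  if (!is.null(.kaks_cache$tables)) return(.kaks_cache$tables)
  codons <- codon_strings()
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  is_stop <- aa == "*"

  ## neighbour index: nb[codon, position, alt 1..3]
  digits <- cbind((0:63) %/% 16L, ((0:63) %/% 4L) %% 4L, (0:63) %% 4L)
  pow <- c(16L, 4L, 1L)
  nb <- array(NA_integer_, dim = c(64L, 3L, 3L))
  for (i in 1:64) {
    for (p in 1:3) {
      alts <- setdiff(0:3, digits[i, p])
      nb[i, p, ] <- i + (alts - digits[i, p]) * pow[p]
    }
  }

  S <- rep(NA_real_, 64L)
  for (i in which(!is_stop)) {
    s <- 0
    for (p in 1:3) {
      nbs <- nb[i, p, ]
      ok <- !is_stop[nbs]
      if (any(ok)) s <- s + sum(aa[nbs[ok]] == aa[i]) / sum(ok)
    }
    S[i] <- s
  }

  perms <- list(
    `1` = matrix(1L, 1L, 1L),
    `2` = rbind(c(1L, 2L), c(2L, 1L)),
    `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )

  Sd <- matrix(NA_real_, 64L, 64L)
  Nd <- matrix(NA_real_, 64L, 64L)
  NP <- matrix(0L, 64L, 64L)
  sense <- which(!is_stop)
  for (a in sense) {
    for (b in sense) {
      if (a == b) {
        Sd[a, b] <- 0; Nd[a, b] <- 0; NP[a, b] <- 1L
        next
      }
      diffpos <- which(digits[a, ] != digits[b, ])
      k <- length(diffpos)
      pm <- perms[[k]]
      s_tot <- 0; n_tot <- 0; nvalid <- 0L
      for (r in seq_len(nrow(pm))) {
        cur <- a
        s <- 0L; n <- 0L
        ok <- TRUE
        for (step in pm[r, ]) {
          p <- diffpos[step]
          nxt <- cur + (digits[b, p] - digits[cur, p]) * pow[p]
          if (is_stop[nxt]) { ok <- FALSE; break }
          if (aa[nxt] == aa[cur]) s <- s + 1L else n <- n + 1L
          cur <- nxt
        }
        if (ok) {
          s_tot <- s_tot + s; n_tot <- n_tot + n; nvalid <- nvalid + 1L
        }
      }
      NP[a, b] <- nvalid
      if (nvalid > 0L) {
        Sd[a, b] <- s_tot / nvalid
        Nd[a, b] <- n_tot / nvalid
      }
    }
  }

  .kaks_cache$tables <- list(codons = codons, aa = aa, is_stop = is_stop,
                             digits = digits, nb = nb, S = S,
                             Sd = Sd, Nd = Nd, NP = NP)
  .kaks_cache$tables
}

codon_index <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  nt <- match(chars, NUCLEOTIDES) - 1L
  n <- length(nt) %/% 3L
  m <- matrix(nt, nrow = 3L)
  idx <- 16L * m[1L, ] + 4L * m[2L, ] + m[3L, ] + 1L
  gap <- matrix(chars, nrow = 3L)
  all_gap <- colSums(gap == "-") == 3L
  idx[all_gap] <- -1L            # gap codon marker
  idx                            # NA for codons with non-ACGT characters
}

#' Fractional synonymous and nonsynonymous site counts of a codon
#'
#' Each of the three positions contributes (synonymous single-nucleotide
#' neighbours) / (non-stop neighbours) synonymous sites; nonsynonymous
#' sites are the complement, so `S + N = 3` for every sense codon.
#'
#' @param codon A single sense codon (string of three of A/C/G/T).
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @export
ng86_site_counts <- function(codon) {
  tb <- ng86_tables()
  i <- match(toupper(codon), tb$codons)
  if (is.na(i)) stop("not a codon: ", codon)
  if (tb$is_stop[i]) stop("stop codon has no site counts: ", codon)
  c(S = tb$S[i], N = 3 - tb$S[i])
}

#' Nei-Gojobori Ka/Ks for one aligned codon pair of sequences
#'
#' Site totals are averaged over the two sequences; per-codon differences
#' are pathway-averaged; proportions are corrected for multiple hits with
#' the Jukes-Cantor formula `d = -(3/4) log(1 - 4p/3)` (undefined when
#' `p >= 3/4`). `omega = Ka/Ks` is missing when Ks is zero or undefined.
#' The selection call is `positive` when omega > 1, `negative` when
#' omega < 1, `neutral` when omega equals 1, and `undefined` when omega is
#' missing.
#'
#' Gap codons (`---`) and codons containing ambiguous characters are
#' skipped, as are the (rare) codon pairs whose mutational pathways all
#' pass through stop codons; the number skipped is reported in the
#' `n_skipped` column. A shared terminal stop codon is trimmed; an internal
#' stop is an error.
#'
#' @param cds_a,cds_b Aligned coding sequences of equal length, a multiple
#'   of 3.
#' @return One-row data.frame: `Ka`, `Ks`, `omega`, `selection`, `S`, `N`,
#'   `Sd`, `Nd`, `n_codons`, `n_skipped`.
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) {
    stop("aligned sequences must have equal length")
  }
  if (nchar(cds_a) %% 3L != 0L) stop("aligned length must be a multiple of 3")
  tb <- ng86_tables()
  ia <- codon_index(cds_a)
  ib <- codon_index(cds_b)

  ## trim a shared terminal stop codon
  n <- length(ia)
  if (n > 0L && !is.na(ia[n]) && !is.na(ib[n]) && ia[n] > 0L && ib[n] > 0L &&
      tb$is_stop[ia[n]] && tb$is_stop[ib[n]]) {
    ia <- ia[-n]; ib <- ib[-n]
  }

  usable <- !is.na(ia) & !is.na(ib) & ia > 0L & ib > 0L
  if (any(usable & (tb$is_stop[pmax(ia, 1L)] | tb$is_stop[pmax(ib, 1L)]))) {
    stop("internal stop codon in ungapped alignment column")
  }
  n_skipped <- sum(!usable)
  ia <- ia[usable]; ib <- ib[usable]

  blocked <- tb$NP[cbind(ia, ib)] == 0L
  if (any(blocked)) {
    n_skipped <- n_skipped + sum(blocked)
    ia <- ia[!blocked]; ib <- ib[!blocked]
  }
  if (length(ia) == 0L) stop("no comparable codon columns")

  S <- (sum(tb$S[ia]) + sum(tb$S[ib])) / 2
  N <- 3 * length(ia) - S
  Sd <- sum(tb$Sd[cbind(ia, ib)])
  Nd <- sum(tb$Nd[cbind(ia, ib)])

  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- if (S > 0) jc(Sd / S) else NA_real_
  Ka <- if (N > 0) jc(Nd / N) else NA_real_
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  selection <- if (is.na(omega)) "undefined"
  else if (omega > 1) "positive"
  else if (omega < 1) "negative"
  else "neutral"

  data.frame(Ka = Ka, Ks = Ks, omega = omega, selection = selection,
             S = S, N = N, Sd = Sd, Nd = Nd,
             n_codons = length(ia), n_skipped = n_skipped,
             stringsAsFactors = FALSE)
}

#' Ka/Ks for a table of duplicate pairs
#'
#' @param pairs data.frame with columns `cds_a`, `cds_b` and any id columns
#'   (e.g. from [read_pair_cds()]).
#' @return `pairs` id columns cbound with the [ng86_kaks()] results, one
#'   row per pair.
#' @export
kaks_table <- function(pairs) {
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ng86_kaks(pairs$cds_a[i], pairs$cds_b[i])
  }))
  ids <- setdiff(names(pairs), c("cds_a", "cds_b"))
  cbind(pairs[, ids, drop = FALSE], res, row.names = NULL)
}

#' Per-species Ks landscape
#'
#' Applies the Ks retention filter (keep `Ks < ks_cutoff`; for the listed
#' exception species keep `Ks > ks_cutoff` instead) and summarizes the
#' retained values as a per-species mean plus a fixed-width histogram.
#'
#' @param ks_by_species data.frame with columns `species_id` and `Ks`.
#' @param ks_cutoff Retention cutoff (default 3).
#' @param exception_species Species for which the complement filter is
#'   applied (e.g. deeply diverged algae whose paralog pairs all exceed the
#'   cutoff).
#' @param bin_width Histogram bin width (default 0.05).
#' @return List with `means` (data.frame `species_id`, `n_retained`,
#'   `mean_ks`; mean is `NA` when nothing survives the filter) and `hist`
#'   (data.frame `species_id`, `bin_start`, `bin_mid`, `count`).
#' @export
ks_landscape <- function(ks_by_species, ks_cutoff = 3,
                         exception_species = character(),
                         bin_width = 0.05) {
  stopifnot(ks_cutoff > 0, bin_width > 0)
  stopifnot(all(c("species_id", "Ks") %in% names(ks_by_species)))
  sp_list <- unique(ks_by_species$species_id)
  means <- list()
  hists <- list()
  for (sp in sp_list) {
    ks <- ks_by_species$Ks[ks_by_species$species_id == sp]
    ks <- ks[!is.na(ks)]
    keep <- if (sp %in% exception_species) ks > ks_cutoff else ks < ks_cutoff
    ks <- ks[keep]
    means[[sp]] <- data.frame(
      species_id = sp, n_retained = length(ks),
      mean_ks = if (length(ks) > 0L) mean(ks) else NA_real_,
      stringsAsFactors = FALSE
    )
    if (length(ks) > 0L) {
      bin <- floor(ks / bin_width)
      tab <- table(bin)
      hists[[sp]] <- data.frame(
        species_id = sp,
        bin_start = as.numeric(names(tab)) * bin_width,
        bin_mid = (as.numeric(names(tab)) + 0.5) * bin_width,
        count = as.integer(tab),
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    means = do.call(rbind, c(means, list(make.row.names = FALSE))),
    hist = if (length(hists) > 0L) {
      do.call(rbind, c(hists, list(make.row.names = FALSE)))
    } else {
      data.frame(species_id = character(), bin_start = numeric(),
                 bin_mid = numeric(), count = integer())
    }
  )
}

#' Fraction of pairs under positive selection
#'
#' @param omega Numeric vector of Ka/Ks values (NA = undefined).
#' @return `count(omega > 1) / count(defined omega)`; `NA` with a warning
#'   when no omega is defined.
#' @export
positive_selection_fraction <- function(omega) {
  defined <- !is.na(omega)
  if (!any(defined)) {
    warning("no defined omega values")
    return(NA_real_)
  }
  sum(omega[defined] > 1) / sum(defined)
}
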