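## Independent brute-force oracles used to pin expected values. Each oracle
## deliberately takes a different computational route than the
## implementation it checks.

## Envelope-merge oracle: explicit residue sets and breadth-first search
## over the pairwise-overlap graph (edge when the shared residues exceed
## half the shorter envelope).
oracle_envelope_components <- function(start, end) {
  n <- length(start)
  if (n == 0L) return(0L)
  residues <- lapply(seq_len(n), function(i) seq(start[i], end[i] - 1L))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- length(intersect(residues[[i]], residues[[j]]))
      if (shared > 0.5 * min(length(residues[[i]]), length(residues[[j]]))) {
        adj[i, j] <- TRUE
      }
    }
  }
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(adj[v, ] & !seen))
    }
  }
  comps
}

## Wilcoxon oracle: full enumeration of group assignments of the pooled
## sample; two-sided p as twice the smaller tail of the rank-sum
## distribution (capped at 1), matching the classical exact definition.
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  idx <- utils::combn(n, nx)
  stats_all <- apply(idx, 2L, function(i) sum(r[i]))
  w_obs <- sum(r[seq_len(nx)])
  p_le <- mean(stats_all <= w_obs)
  p_ge <- mean(stats_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

## NG86 codon oracle: string-based recursive enumeration of all minimal
## single-step mutation paths between two codons, skipping paths through
## stops; site counts by explicit neighbour substitution.
oracle_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc), names(gc))
}

oracle_site_counts <- function(codon, code = oracle_genetic_code()) {
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    syn <- 0; nonstop <- 0
    for (b in setdiff(nts, substr(codon, p, p))) {
      nb <- codon
      substr(nb, p, p) <- b
      if (code[[nb]] == "*") next
      nonstop <- nonstop + 1
      if (code[[nb]] == code[[codon]]) syn <- syn + 1
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  c(S = s, N = 3 - s)
}

oracle_path_counts <- function(a, b, code = oracle_genetic_code()) {
  recurse <- function(cur) {
    diffs <- which(strsplit(cur, "")[[1L]] != strsplit(b, "")[[1L]])
    if (length(diffs) == 0L) {
      return(list(c(s = 0, n = 0, k = 1)))
    }
    out <- list()
    for (p in diffs) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (code[[nxt]] == "*") next
      step <- if (code[[nxt]] == code[[cur]]) c(1, 0) else c(0, 1)
      for (tail in recurse(nxt)) {
        out[[length(out) + 1L]] <- c(s = step[1] + tail[["s"]],
                                     n = step[2] + tail[["n"]], k = 1)
      }
    }
    out
  }
  paths <- recurse(a)
  if (length(paths) == 0L) {
    return(c(Sd = NA_real_, Nd = NA_real_, n_paths = 0))
  }
  m <- do.call(rbind, paths)
  c(Sd = mean(m[, "s"]), Nd = mean(m[, "n"]), n_paths = nrow(m))
}

## Interval-union oracle: per-base boolean coverage.
oracle_union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  hi <- max(end)
  covered <- rep(FALSE, hi)
  for (i in seq_along(start)) {
    covered[seq(start[i] + 1L, end[i])] <- TRUE
  }
  sum(covered)
}

## Pearson r^2 from the closed-form sums.
oracle_pearson_r2 <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

## Shared fixture: a small hit table for one protein.
make_hits <- function(e_value, env_start, env_end,
                      protein_id = "p1",
                      domain_name = "Myb_DNA-binding") {
  data.frame(protein_id = protein_id, domain_name = domain_name,
             e_value = e_value, env_start = env_start, env_end = env_end,
             score = 50, stringsAsFactors = FALSE)
}
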