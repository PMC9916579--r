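## Generators for every pipeline input, each with planted ground truth, so
## all stages can be exercised end-to-end without external data. Every
## generator takes an explicit seed and is byte-identical for a fixed
## (seed, configuration).

#' Simulate a domain-hit table with planted repeat counts
#'
#' True repeats are laid out as ~52-residue envelopes separated by short
#' linkers, each with an E-value comfortably below the threshold. Decoy
#' hits (failing the E-value filter) and near-duplicate envelopes
#' (overlapping a true repeat by more than half its length, so they merge
#' away) are planted to exercise the filter and the merge rule.
#'
#' @param n_proteins Number of proteins.
#' @param count_probs Probabilities of planted repeat counts 0..4.
#' @param e_threshold The downstream inclusion threshold the decoys must
#'   fail (default 1e-5).
#' @param decoy_prob Probability a protein receives a decoy hit.
#' @param dup_prob Probability a true repeat envelope is emitted twice
#'   (split/duplicated envelope).
#' @param seed Random seed.
#' @return List with `hits` (data.frame in the [read_domain_hits()] layout)
#'   and `truth` (data.frame `protein_id`, `repeat_count`, including
#'   planted zeros).
#' @export
simulate_domain_hits <- function(n_proteins = 100,
                                 count_probs = c(0.15, 0.45, 0.3, 0.06, 0.04),
                                 e_threshold = 1e-5,
                                 decoy_prob = 0.3, dup_prob = 0.15,
                                 seed = 1) {
  stopifnot(length(count_probs) == 5L, e_threshold > 0)
  set.seed(seed)
  ids <- sprintf("p%04d", seq_len(n_proteins))
  counts <- sample(0:4, n_proteins, replace = TRUE, prob = count_probs)
  rows <- list()
  for (i in seq_len(n_proteins)) {
    k <- counts[i]
    if (k > 0L) {
      for (r in seq_len(k)) {
        s <- (r - 1L) * 62L
        e <- s + 52L
        ev <- 10^stats::runif(1L, -30, log10(e_threshold) - 1)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = ids[i], domain_name = MYB_DOMAIN_NAME,
          e_value = ev, env_start = s, env_end = e,
          score = round(stats::runif(1L, 30, 200), 1),
          stringsAsFactors = FALSE
        )
        if (stats::runif(1L) < dup_prob) {
          ## duplicated envelope shifted a few residues: overlap >> 50%
          sh <- sample(1:8, 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = ids[i], domain_name = MYB_DOMAIN_NAME,
            e_value = 10^stats::runif(1L, -20, log10(e_threshold) - 1),
            env_start = s + sh, env_end = e + sh,
            score = round(stats::runif(1L, 20, 100), 1),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    if (stats::runif(1L) < decoy_prob) {
      s <- sample(0:400, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = ids[i], domain_name = MYB_DOMAIN_NAME,
        e_value = 10^stats::runif(1L, log10(e_threshold) + 0.5, -1),
        env_start = s, env_end = s + 52L,
        score = round(stats::runif(1L, 5, 20), 1),
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(rows) > 0L) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    empty_domain_hits()
  }
  list(
    hits = hits,
    truth = data.frame(protein_id = ids, repeat_count = counts,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate an aligned codon pair evolved at a known omega
#'
#' One sequence is drawn uniformly over sense codons; the other is evolved
#' from it by repeated single-nucleotide proposals (uniform position,
#' uniform alternative base). Proposals creating stop codons are rejected;
#' synonymous and nonsynonymous proposals are accepted with probabilities
#' in the ratio `1 : omega`. The proposal budget is calibrated so `t`
#' approximates the expected number of synonymous substitutions per
#' synonymous site. The mutation mechanism (independent sites, uniform
#' base rates) matches the assumptions of the counting estimator, so
#' recovery tests isolate estimator correctness rather than model
#' mismatch.
#'
#' @param omega Planted Ka/Ks (>= 0; 0 forbids nonsynonymous change).
#' @param t Expected synonymous substitutions per synonymous site
#'   (default 0.3).
#' @param n_codons Number of codons (>= 1).
#' @param seed Random seed.
#' @return List with `cds_a`, `cds_b` (character), `omega`, `t`.
#' @export
simulate_codon_pair <- function(omega, t = 0.3, n_codons = 300, seed = 1) {
  stopifnot(omega >= 0, t >= 0, n_codons >= 1)
  set.seed(seed)
  tb <- ng86_tables()
  sense <- which(!tb$is_stop)
  anc <- sample(sense, n_codons, replace = TRUE)
  cur <- anc
  if (t > 0) {
    ps <- if (omega > 1) 1 / omega else 1
    pn <- min(1, omega)
    ## ~3 proposals per codon produce ~1 accepted synonymous change per
    ## synonymous site when ps = 1 (see vignette for the calibration)
    k <- stats::rpois(n_codons, 3 * t / ps)
    for (round in seq_len(max(k, 0L))) {
      act <- which(k >= round)
      if (length(act) == 0L) break
      pos <- sample.int(3L, length(act), replace = TRUE)
      alt <- sample.int(3L, length(act), replace = TRUE)
      prop <- tb$nb[cbind(cur[act], pos, alt)]
      ok <- !tb$is_stop[prop]
      syn <- tb$aa[prop] == tb$aa[cur[act]]
      acc_p <- ifelse(syn, ps, pn)
      u <- stats::runif(length(act))
      accept <- ok & (u < acc_p)
      cur[act[accept]] <- prop[accept]
    }
  }
  list(
    cds_a = paste(tb$codons[anc], collapse = ""),
    cds_b = paste(tb$codons[cur], collapse = ""),
    omega = omega, t = t
  )
}

#' Simulate a tissue expression matrix with planted duplicate fates
#'
#' Counts are negative binomial around a per-pair baseline whose RPKM sits
#' well above the expression threshold. SNFD pairs receive reciprocal
#' tissue-specific fold effects (each gene up in one tissue); AED pairs
#' receive a one-directional fold effect in `ceiling(tissues/3)` tissues;
#' NDD pairs share means everywhere.
#'
#' @param n_pairs Number of duplicate pairs.
#' @param fate_props Named proportions for SNFD/AED/NDD (sum to 1).
#' @param tissues Number of tissues (default 6).
#' @param replicates Replicates per tissue (default 3).
#' @param effect_fold Planted fold effect (default 8).
#' @param dispersion Negative-binomial dispersion (default 0.1; variance
#'   `mu + dispersion * mu^2`).
#' @param base_rpkm_meanlog,base_rpkm_sdlog Log-normal parameters of the
#'   per-pair baseline RPKM (defaults give a median of 50).
#' @param seed Random seed.
#' @return List: `counts` (genes x libraries), `lib_meta`, `gene_lengths`
#'   (named), `pairs` (data.frame `gene_a`, `gene_b`), `truth`
#'   (`gene_a`, `gene_b`, `fate`).
#' @export
simulate_expression <- function(n_pairs = 300,
                                fate_props = c(SNFD = 0.25, AED = 0.45,
                                               NDD = 0.30),
                                tissues = 6, replicates = 3,
                                effect_fold = 8, dispersion = 0.1,
                                base_rpkm_meanlog = log(50),
                                base_rpkm_sdlog = 0.5,
                                seed = 1) {
  stopifnot(abs(sum(fate_props) - 1) < 1e-8, tissues >= 2, replicates >= 1,
            effect_fold > 0, dispersion >= 0)
  stopifnot(all(names(fate_props) %in% FATE_LEVELS))
  set.seed(seed)
  n_per <- floor(fate_props * n_pairs)
  rem <- n_pairs - sum(n_per)
  if (rem > 0) {
    extra <- order(fate_props * n_pairs - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[extra] <- n_per[extra] + 1L
  }
  fates <- rep(names(n_per), n_per)

  gene_a <- sprintf("g%04da", seq_len(n_pairs))
  gene_b <- sprintf("g%04db", seq_len(n_pairs))
  genes <- c(rbind(gene_a, gene_b))
  lens <- stats::setNames(sample(600:3000, 2L * n_pairs, replace = TRUE), genes)

  tiss <- paste0("tissue", seq_len(tissues))
  libs <- as.vector(outer(tiss, seq_len(replicates),
                          function(t, r) paste0(t, "_r", r)))
  lib_tissue <- rep(tiss, times = replicates)
  lib_sizes <- round(2e7 * stats::runif(length(libs), 0.8, 1.2))
  names(lib_sizes) <- libs

  base_rpkm <- stats::rlnorm(n_pairs, base_rpkm_meanlog, base_rpkm_sdlog)
  ## per-gene, per-tissue fold multipliers
  fold_a <- matrix(1, n_pairs, tissues)
  fold_b <- matrix(1, n_pairs, tissues)
  need <- ceiling(tissues / 3)
  for (i in seq_len(n_pairs)) {
    if (fates[i] == "SNFD") {
      up <- sample(tissues, 2L)
      fold_a[i, up[1L]] <- effect_fold
      fold_b[i, up[2L]] <- effect_fold
    } else if (fates[i] == "AED") {
      up <- sample(tissues, need)
      if (stats::runif(1L) < 0.5) fold_a[i, up] <- effect_fold
      else fold_b[i, up] <- effect_fold
    }
  }

  counts <- matrix(0L, nrow = 2L * n_pairs, ncol = length(libs),
                   dimnames = list(genes, libs))
  size <- if (dispersion > 0) 1 / dispersion else Inf
  for (j in seq_along(libs)) {
    ti <- match(lib_tissue[j], tiss)
    mu_a <- base_rpkm * fold_a[, ti] * lens[gene_a] * lib_sizes[j] / 1e9
    mu_b <- base_rpkm * fold_b[, ti] * lens[gene_b] * lib_sizes[j] / 1e9
    mu <- as.vector(rbind(mu_a, mu_b))
    counts[, j] <- if (is.finite(size)) {
      stats::rnbinom(length(mu), mu = mu, size = size)
    } else {
      stats::rpois(length(mu), mu)
    }
  }

  list(
    counts = counts,
    lib_meta = data.frame(
      library = libs, tissue = lib_tissue,
      replicate = rep(seq_len(replicates), each = tissues),
      total_mapped_reads = unname(lib_sizes),
      stringsAsFactors = FALSE
    ),
    gene_lengths = lens,
    pairs = data.frame(gene_a = gene_a, gene_b = gene_b,
                       stringsAsFactors = FALSE),
    truth = data.frame(gene_a = gene_a, gene_b = gene_b, fate = fates,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a kingdom-labeled gene tree with planted transfers
#'
#' Builds a tree whose plant and fungal genes start out reciprocally
#' monophyletic, then plants `n_transfers` horizontal transfers by placing
#' a tip of one kingdom on a pendant branch inside the other kingdom's
#' clade. All internal nodes carry the same bootstrap support label.
#'
#' @param n_plant,n_fungi Tips per kingdom (totals after transfers are
#'   unchanged).
#' @param n_transfers Number of planted transfers
#'   (<= `min(n_plant, n_fungi) / 2`).
#' @param support Bootstrap support written on every internal node.
#' @param seed Random seed.
#' @return List: `tree` (`phylo`), `kingdoms` (named vector), `truth`
#'   (data.frame `gene_id`, `direction`).
#' @export
simulate_gene_tree_with_hgt <- function(n_plant = 15, n_fungi = 15,
                                        n_transfers = 1, support = 100,
                                        seed = 1) {
  stopifnot(n_plant >= 3, n_fungi >= 3,
            n_transfers <= min(n_plant, n_fungi) / 2)
  set.seed(seed)
  n_from_plant <- if (n_transfers > 0) sum(stats::runif(n_transfers) < 0.5) else 0L
  n_from_fungi <- n_transfers - n_from_plant
  ## a transferred "plant" tip is a plant gene sitting inside the fungal
  ## clade (direction fungi_to_plant reads: acquired from the surrounding
  ## fungal donors)
  plant_resident <- n_plant - n_from_plant
  fungi_resident <- n_fungi - n_from_fungi
  pt <- ape::rtree(plant_resident,
                   tip.label = sprintf("plant%02d", seq_len(plant_resident)))
  ft <- ape::rtree(fungi_resident,
                   tip.label = sprintf("fungus%02d", seq_len(fungi_resident)))
  backbone <- ape::read.tree(text = "(P:1,F:1);")
  tree <- ape::bind.tree(backbone, pt, where = which(backbone$tip.label == "P"))
  tree <- ape::bind.tree(tree, ft, where = which(tree$tip.label == "F"))

  truth <- data.frame(gene_id = character(), direction = character(),
                      stringsAsFactors = FALSE)
  graft <- function(tree, new_tip, host_prefix) {
    hosts <- grep(paste0("^", host_prefix), tree$tip.label, value = TRUE)
    host <- sample(hosts, 1L)
    where <- which(tree$tip.label == host)
    el <- tree$edge.length[tree$edge[, 2L] == where]
    phytools::bind.tip(tree, new_tip, edge.length = el / 2,
                       where = where, position = el / 2)
  }
  if (n_from_plant > 0) {
    for (i in seq_len(n_from_plant)) {
      tip <- sprintf("plant%02d", plant_resident + i)
      tree <- graft(tree, tip, "fungus")
      truth <- rbind(truth, data.frame(gene_id = tip,
                                       direction = "fungi_to_plant",
                                       stringsAsFactors = FALSE))
    }
  }
  if (n_from_fungi > 0) {
    for (i in seq_len(n_from_fungi)) {
      tip <- sprintf("fungus%02d", fungi_resident + i)
      tree <- graft(tree, tip, "plant")
      truth <- rbind(truth, data.frame(gene_id = tip,
                                       direction = "plant_to_fungi",
                                       stringsAsFactors = FALSE))
    }
  }
  tree$node.label <- rep(as.character(support), tree$Nnode)
  kingdoms <- stats::setNames(
    ifelse(grepl("^plant", tree$tip.label), "plant", "fungus_oomycete"),
    tree$tip.label
  )
  list(tree = tree, kingdoms = kingdoms, truth = truth)
}

#' Simulate a TE annotation with planted insertion-time peaks
#'
#' LTR identities are derived from insertion times drawn around the
#' requested peaks via `identity = 1 - 2 mu T`; intervals are laid out on
#' a synthetic contig. When a region layout with planted coverages is
#' given, one TE block per region is placed to realize the requested
#' occurrence rate exactly.
#'
#' @param peaks_my Peak insertion times in million years.
#' @param peak_sd_frac Relative spread of times around each peak
#'   (default 0.15).
#' @param mu Substitution rate per site per year (default 1e-8).
#' @param n_per_peak Intact LTR elements per peak (default 500).
#' @param region_layout Optional data.frame (`region_id`, `contig_id`,
#'   `start`, `end`, `coverage`) describing regions and the ORT to plant in
#'   each.
#' @param seed Random seed.
#' @return List: `te` (data.frame `contig_id`, `start`, `end`, `te_class`,
#'   `identity`), `truth` (list with `times_my` per element and the echoed
#'   `region_layout`).
#' @export
simulate_te_annotation <- function(peaks_my = c(0.079, 1.376),
                                   peak_sd_frac = 0.15, mu = 1e-8,
                                   n_per_peak = 500, region_layout = NULL,
                                   seed = 1) {
  stopifnot(all(peaks_my > 0), mu > 0, n_per_peak >= 1)
  set.seed(seed)
  times <- unlist(lapply(peaks_my, function(p) {
    abs(stats::rnorm(n_per_peak, p, peak_sd_frac * p))
  }))
  identity <- 1 - 2 * mu * times * 1e6
  stopifnot(all(identity >= 0))
  n <- length(times)
  lens <- round(stats::runif(n, 2500, 7500))
  gaps <- round(stats::runif(n, 500, 2000))
  starts <- cumsum(c(0L, (lens + gaps)[-n]))
  te <- data.frame(
    contig_id = "ltr_contig",
    start = starts, end = starts + lens,
    te_class = sample(c("Gypsy", "Copia"), n, replace = TRUE,
                      prob = c(0.7, 0.3)),
    identity = identity,
    stringsAsFactors = FALSE
  )
  if (!is.null(region_layout)) {
    stopifnot(all(c("region_id", "contig_id", "start", "end", "coverage")
                  %in% names(region_layout)))
    stopifnot(all(region_layout$coverage >= 0 & region_layout$coverage <= 1))
    blocks <- region_layout[region_layout$coverage > 0, , drop = FALSE]
    if (nrow(blocks) > 0L) {
      cov_len <- round(blocks$coverage * (blocks$end - blocks$start))
      te <- rbind(te, data.frame(
        contig_id = blocks$contig_id,
        start = blocks$start, end = blocks$start + cov_len,
        te_class = "hAT", identity = NA_real_,
        stringsAsFactors = FALSE
      ))
      region_layout$coverage <- ifelse(
        region_layout$coverage > 0,
        round(region_layout$coverage * (region_layout$end - region_layout$start)) /
          (region_layout$end - region_layout$start),
        0
      )
    }
  }
  list(
    te = te,
    truth = list(times_my = times, region_layout = region_layout)
  )
}

#' Write a TE table as GFF3
#'
#' Emits an EDTA-style GFF3 (`Classification=` and `ltr_identity=`
#' attributes) that [read_te_gff()] reads back.
#'
#' @param te data.frame as produced by [simulate_te_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_gff <- function(te, path) {
  so <- c(Gypsy = "Gypsy_LTR_retrotransposon",
          Copia = "Copia_LTR_retrotransposon",
          other_LTR = "LTR_retrotransposon",
          hAT = "hAT_TIR_transposon", Mutator = "Mutator_TIR_transposon",
          CACTA = "CACTA_TIR_transposon",
          other_TIR = "PIF_Harbinger_TIR_transposon",
          Helitron = "helitron", other = "repeat_region")
  cls2class <- c(Gypsy = "LTR/Gypsy", Copia = "LTR/Copia",
                 other_LTR = "LTR/unknown", hAT = "DNA/DTA",
                 Mutator = "DNA/DTM", CACTA = "DNA/DTC",
                 other_TIR = "DNA/DTH", Helitron = "DNA/Helitron",
                 other = "Unknown")
  attrs <- sprintf("ID=te%05d;Classification=%s", seq_len(nrow(te)),
                   cls2class[te$te_class])
  has_id <- !is.na(te$identity)
  attrs[has_id] <- paste0(attrs[has_id],
                          sprintf(";ltr_identity=%.6f", te$identity[has_id]))
  lines <- sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t+\t.\t%s",
                   te$contig_id, so[te$te_class],
                   te$start + 1L, te$end, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
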