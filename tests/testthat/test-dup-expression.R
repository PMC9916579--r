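test_that("rpkm implements count * 1e9 / (length * library size)", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 500, 1e7), 0)
  expect_equal(rpkm(10, 2000, 1e6), 5)
  expect_error(rpkm(1, 0, 1e6), "gene_length")
  expect_error(rpkm(1, 100, 0), "total_mapped_reads")
})

test_that("expressed ratio uses a strict threshold and is monotone in it", {
  expect_equal(expressed_ratio(c(6, 4, 10), 5), 2 / 3)
  expect_equal(expressed_ratio(c(5, 5), 5), 0)
  expect_equal(expressed_ratio(c(7, 8), 5), 1)
  expect_error(expressed_ratio(numeric(0)), "at least one")
  set.seed(9)
  x <- rexp(50, 1 / 10)
  ths <- sort(runif(8, 0, 30))
  ratios <- vapply(ths, function(t) expressed_ratio(x, t), numeric(1L))
  expect_true(all(diff(ratios) <= 0))
})

make_pair_matrix <- function(counts_a, counts_b, tissues, reps) {
  libs <- as.vector(outer(paste0("t", seq_len(tissues)), seq_len(reps),
                          function(t, r) paste0(t, "_r", r)))
  counts <- rbind(a = rep(counts_a, reps), b = rep(counts_b, reps))
  colnames(counts) <- libs
  list(
    counts = counts,
    lib_meta = data.frame(library = libs,
                          tissue = rep(paste0("t", seq_len(tissues)), reps),
                          replicate = rep(seq_len(reps), each = tissues),
                          total_mapped_reads = 1e6),
    lens = c(a = 1000, b = 1000),
    pairs = data.frame(gene_a = "a", gene_b = "b")
  )
}

test_that("identical counts give no verdict; silent pairs are excluded", {
  m <- make_pair_matrix(rep(100, 3), rep(100, 3), tissues = 3, reps = 3)
  tests <- suppressMessages(test_duplicate_pairs(
    m$pairs, m$counts, m$lib_meta, m$lens))
  expect_true(all(tests$verdict == "none"))
  ## both genes below RPKM 5 everywhere -> excluded (verdict NA, fate NA)
  m2 <- make_pair_matrix(rep(1, 3), rep(1, 3), tissues = 3, reps = 3)
  expect_message(
    tests2 <- test_duplicate_pairs(m2$pairs, m2$counts, m2$lib_meta, m2$lens),
    "unexpressed"
  )
  expect_true(all(is.na(tests2$verdict)))
  expect_true(is.na(classify_fates(tests2)$fate))
})

test_that("single-replicate tissues use the fold-change-only rule", {
  ## ratio 1.5 < FC 2 -> none even though consistent
  m <- make_pair_matrix(c(150, 150), c(100, 100), tissues = 2, reps = 1)
  tests <- suppressMessages(test_duplicate_pairs(
    m$pairs, m$counts, m$lib_meta, m$lens))
  expect_true(all(tests$verdict == "none"))
  ## a clear 8-fold difference passes without replicates
  m2 <- make_pair_matrix(c(800, 800), c(100, 100), tissues = 2, reps = 1)
  tests2 <- suppressMessages(test_duplicate_pairs(
    m2$pairs, m2$counts, m2$lib_meta, m2$lens))
  expect_true(all(tests2$verdict == "a_higher"))
})

test_that("a planted large effect with replicates yields the right verdict", {
  sim <- simulate_expression(n_pairs = 40, tissues = 4, replicates = 3,
                             fate_props = c(SNFD = 0, AED = 1, NDD = 0),
                             seed = 21)
  tests <- suppressMessages(test_duplicate_pairs(
    sim$pairs, sim$counts, sim$lib_meta, sim$gene_lengths))
  ## every AED pair shows at least one directional verdict
  per_pair <- split(tests$verdict, tests$gene_a)
  expect_true(all(vapply(per_pair,
                         function(v) any(v != "none"), logical(1L))))
})

test_that("fate rules: SNFD first, AED needs a third of tissues, else NDD", {
  expect_equal(classify_fate(c(root = "a_higher", leaf = "b_higher")), "SNFD")
  expect_equal(classify_fate(c("a_higher", "a_higher", rep("none", 4))), "AED")
  expect_equal(classify_fate(rep("none", 4)), "NDD")
  ## one directional tissue of six is below the ceiling(6/3) = 2 AED bar
  expect_equal(classify_fate(c("a_higher", rep("none", 5))), "NDD")
  ## a single opposing tissue disqualifies AED in favour of SNFD
  expect_equal(classify_fate(c("a_higher", "a_higher", "b_higher", "none")),
               "SNFD")
  expect_warning(out <- classify_fate(c(root = "a_higher")), "two tissues")
  expect_true(is.na(out))
})

test_that("fates partition pairs and are invariant to gene relabeling", {
  sim <- simulate_expression(n_pairs = 60, seed = 14)
  tests <- suppressMessages(test_duplicate_pairs(
    sim$pairs, sim$counts, sim$lib_meta, sim$gene_lengths))
  fates <- classify_fates(tests)
  expect_true(all(fates$fate %in% c("SNFD", "AED", "NDD")))
  expect_equal(nrow(fates), 60L)
  ## swap a and b: same fate labels
  swapped <- data.frame(gene_a = sim$pairs$gene_b, gene_b = sim$pairs$gene_a)
  tests_sw <- suppressMessages(test_duplicate_pairs(
    swapped, sim$counts, sim$lib_meta, sim$gene_lengths))
  fates_sw <- classify_fates(tests_sw)
  expect_equal(fates_sw$fate, fates$fate)
})

test_that("planted NDD pairs rarely receive any verdict", {
  sim <- simulate_expression(n_pairs = 100, seed = 3,
                             fate_props = c(SNFD = 0, AED = 0, NDD = 1))
  tests <- suppressMessages(test_duplicate_pairs(
    sim$pairs, sim$counts, sim$lib_meta, sim$gene_lengths))
  false_rate <- mean(tests$verdict != "none")
  expect_lte(false_rate, 0.05)
})

test_that("fate-conservation matrix distinguishes SNFD, presence, absence", {
  og <- data.frame(og_id = c("og1", "og1", "og1", "og1", "og2"),
                   species_id = c("spA", "spA", "spB", "spB", "spB"),
                   gene_id = c("a1", "a2", "b1", "b2", "b3"))
  fates <- data.frame(
    gene_a = c("a1", "b1"), gene_b = c("a2", "b2"),
    fate = c("SNFD", "NDD"), species_id = c("spA", "spB")
  )
  m <- fate_conservation_matrix(fates, og, c("spA", "spB", "spC"))
  expect_equal(m["spA", "og1"], "SNFD")
  expect_equal(m["spB", "og1"], "present-not-SNFD")
  expect_equal(m["spC", "og1"], "absent")
  expect_equal(m["spA", "og2"], "absent")
})
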