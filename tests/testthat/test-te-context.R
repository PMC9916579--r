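test_that("interval merging matches examples and the per-base oracle", {
  m <- merge_intervals(data.frame(start = c(1, 50), end = c(100, 150)))
  expect_equal(m, data.frame(start = 1, end = 150), ignore_attr = TRUE)
  expect_equal(interval_union_length(data.frame(start = c(1, 50),
                                                end = c(100, 150))), 149)
  disjoint <- data.frame(start = c(0, 20), end = c(10, 30))
  expect_equal(merge_intervals(disjoint), disjoint, ignore_attr = TRUE)
  expect_equal(interval_union_length(disjoint), 20)
  set.seed(77)
  for (case in 1:25) {
    n <- sample(1:50, 1)
    s <- sample(0:500, n, replace = TRUE)
    e <- s + sample(1:80, n, replace = TRUE)
    expect_equal(interval_union_length(data.frame(start = s, end = e)),
                 oracle_union_length(s, e))
    ## order invariance
    p <- sample(n)
    expect_equal(
      merge_intervals(data.frame(start = s[p], end = e[p])),
      merge_intervals(data.frame(start = s, end = e))
    )
  }
})

test_that("flanks are strand aware and truncated at contig bounds", {
  fl <- flank_regions(6000, 8000, "+", 20000)
  expect_equal(fl[fl$region == "upstream_5kb", c("start", "end")],
               data.frame(start = 1000, end = 6000), ignore_attr = TRUE)
  expect_equal(fl[fl$region == "downstream_5kb", c("start", "end")],
               data.frame(start = 8000, end = 13000), ignore_attr = TRUE)
  fl2 <- flank_regions(2000, 3000, "+", 20000)
  expect_equal(fl2[fl2$region == "upstream_5kb", c("start", "end")],
               data.frame(start = 0, end = 2000), ignore_attr = TRUE)
  fl3 <- flank_regions(6000, 8000, "-", 20000)
  expect_equal(fl3[fl3$region == "upstream_5kb", c("start", "end")],
               data.frame(start = 8000, end = 13000), ignore_attr = TRUE)
})

test_that("occurrence rate is the union overlap fraction, bounded in [0,1]", {
  region <- data.frame(start = 0, end = 1000)
  te <- data.frame(start = c(100, 200), end = c(300, 350))
  expect_equal(occurrence_rate(region, te), 0.25)
  expect_equal(occurrence_rate(region, te[0, ]), 0)
  cover <- data.frame(start = c(0, 400, -50), end = c(600, 1200, 500))
  expect_equal(occurrence_rate(region, cover), 1)
  expect_message(out <- occurrence_rate(region[region$start > 0, ], te),
                 "empty region")
  expect_true(is.na(out))
  ## monotone non-decreasing as TEs are added
  set.seed(4)
  ort <- numeric(0)
  acc <- data.frame(start = integer(0), end = integer(0))
  for (i in 1:10) {
    s <- sample(0:900, 1)
    acc <- rbind(acc, data.frame(start = s, end = s + 100))
    ort <- c(ort, occurrence_rate(region, acc))
  }
  expect_true(all(diff(ort) >= 0))
  expect_true(all(ort >= 0 & ort <= 1))
})

test_that("LTR dating is linear in divergence and inverse in mu", {
  expect_equal(ltr_insertion_time(1), 0)
  expect_equal(ltr_insertion_time(0.99842, 1e-8), 0.079)
  expect_equal(ltr_insertion_time(0.97248, 1e-8), 1.376)
  ids <- runif(20, 0.9, 1)
  expect_equal(ltr_insertion_time(ids, 5e-9), 2 * ltr_insertion_time(ids, 1e-8))
  expect_error(ltr_insertion_time(1.2), "identity")
  expect_error(ltr_insertion_time(0.9, 0), "mu")
})

test_that("ORT-expression correlation is Pearson r^2 per fate class", {
  x <- c(0.1, 0.22, 0.35, 0.4, 0.55)
  y <- c(12, 18, 20, 31, 36)
  rec <- data.frame(gene_id = paste0("g", 1:5), region = "upstream_5kb",
                    ort = x)
  fate <- setNames(rep("SNFD", 5), paste0("g", 1:5))
  res <- ort_expression_correlation(rec, setNames(y, paste0("g", 1:5)), fate)
  expect_equal(res$r_squared[res$fate == "SNFD"], oracle_pearson_r2(x, y))
  ## exact proportionality -> r^2 = 1
  res1 <- ort_expression_correlation(rec, setNames(10 * x + 6, paste0("g", 1:5)),
                                     fate)
  expect_equal(res1$r_squared[res1$fate == "SNFD"], 1)
  ## constant ORT -> missing
  rec$ort <- 0.3
  res2 <- ort_expression_correlation(rec, setNames(y, paste0("g", 1:5)), fate)
  expect_true(is.na(res2$r_squared[res2$fate == "SNFD"]))
  ## genes failing RPKM > 5 are dropped; < 3 genes -> missing
  rec$ort <- x
  res3 <- ort_expression_correlation(rec, setNames(c(6, 7, 1, 1, 1),
                                                   paste0("g", 1:5)), fate)
  expect_true(is.na(res3$r_squared[res3$fate == "SNFD"]))
})

test_that("TE GFF3 round-trips classes and LTR identities", {
  sim <- simulate_te_annotation(peaks_my = 0.5, n_per_peak = 30, seed = 6)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_te_gff(sim$te, path)
  back <- read_te_gff(path)
  expect_equal(back$te_class, sim$te$te_class)
  expect_equal(back$start, sim$te$start)
  expect_equal(back$identity, sim$te$identity, tolerance = 1e-6)
  expect_equal(te_class_map(c("Gypsy_LTR_retrotransposon", "DNA/DTA",
                              "weird_thing")),
               c("Gypsy", "hAT", "other"))
})

test_that("ORT table covers genic and flank regions per gene", {
  genes <- data.frame(gene_id = "gX", contig_id = "c1", strand = "+",
                      start = 6000, end = 8000)
  te <- data.frame(contig_id = "c1", start = c(1000, 7000), end = c(3500, 7500))
  ort <- ort_table(genes, te, c(c1 = 20000))
  expect_equal(ort$region, c("genic", "upstream_5kb", "downstream_5kb"))
  expect_equal(ort$ort, c(0.25, 0.5, 0))
})
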