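test_that("species table derives the group from the lineage category", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_file(data.frame(
    species_id = c("sp1", "sp2", "sp3"),
    category = c("Bryophyta", "Fabids", "Gymnospermae")
  ), path)
  meta <- read_species_table(path)
  expect_equal(meta$group, c("non-flowering", "flowering", "non-flowering"))
  expect_equal(nrow(lineage_categories()), 22L)
  expect_equal(unname(table(lineage_categories()$group)), c(11L, 11L),
               ignore_attr = TRUE)
})

test_that("unknown categories and duplicate species are rejected by name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_file(data.frame(species_id = "sp3", category = "Dinosauria"), path)
  expect_error(read_species_table(path), "Dinosauria")
  write_tsv_file(data.frame(species_id = c("a", "a"),
                            category = c("Fabids", "Fabids")), path)
  expect_error(read_species_table(path), "duplicated")
})

test_that("longest isoform wins, with lexicographic tie-breaking", {
  gm <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    transcript_id = c("t1", "t2", "tB", "tA", "solo"),
    length = c(100, 250, 200, 200, 50)
  )
  sel <- select_longest_isoform(gm)
  expect_equal(sel[["g1"]], "t2")
  expect_equal(sel[["g2"]], "tA")   # tie: lexicographically smaller id
  expect_equal(sel[["g3"]], "solo")
  expect_error(select_longest_isoform(gm[0, ]), "at least one")
  gm$length[1] <- 0
  expect_error(select_longest_isoform(gm), "positive")
})

test_that("domtblout envelopes are converted to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".txt")
  line <- paste("prot1 - 300 Myb_DNA-binding PF00249.33 52",
                "1e-20 60 0.1 1 2 1e-9 1e-7 30 0.1 1 52 4 55 5 56 0.9 -")
  writeLines(c("# comment", line, "#"), path)
  hits <- read_domain_hits(path, "domtblout")
  expect_equal(hits$env_start, 4L)
  expect_equal(hits$env_end, 56L)
  expect_equal(hits$e_value, 1e-7)   # per-domain independent E-value
  expect_equal(hits$protein_id, "prot1")
})

test_that("empty and malformed domain-hit inputs behave as specified", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("# only comments", path)
  expect_equal(nrow(read_domain_hits(path, "domtblout")), 0L)
  writeLines("too few fields", path)
  expect_error(read_domain_hits(path, "domtblout"), "line 1")
})

test_that("simple_tsv hits parse and round-trip identically", {
  hits <- make_hits(e_value = c(1e-7, 2e-6), env_start = c(10, 70),
                    env_end = c(60, 120))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_domain_hits(hits, path)
  back <- read_domain_hits(path, "simple_tsv")
  expect_equal(back, hits)
})

test_that("coordinate conversions are mutually inverse", {
  for (i in 1:20) {
    s1 <- i; e1 <- i + sample(1:50, 1)
    z <- coords_to_zero_based(s1, e1)
    o <- coords_to_one_based(z$start, z$end)
    expect_equal(o, list(start = s1, end = e1))
  }
  ## 1-based inclusive [5, 56] is 0-based half-open [4, 56)
  expect_equal(coords_to_zero_based(5L, 56L), list(start = 4L, end = 56L))
})

test_that("orthogroup tables round-trip through the OrthoFinder dialect", {
  og <- data.frame(
    og_id = c("OG1", "OG1", "OG1", "OG2", "OG2"),
    species_id = c("spA", "spA", "spB", "spB", "spC"),
    gene_id = c("a1", "a2", "b1", "b2", "c1")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_orthogroups(og, path)
  back <- read_orthogroups(path)
  expect_equal(back[order(back$og_id, back$species_id, back$gene_id), ],
               og[order(og$og_id, og$species_id, og$gene_id), ],
               ignore_attr = TRUE)
})

test_that("GFF3 gene models yield exon-summed transcript lengths", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t5000\t.\t+\t.\tID=gX",
    "chr1\tsrc\tmRNA\t1001\t5000\t.\t+\t.\tID=gX.t1;Parent=gX",
    "chr1\tsrc\texon\t1001\t2000\t.\t+\t.\tID=e1;Parent=gX.t1",
    "chr1\tsrc\texon\t4001\t5000\t.\t+\t.\tID=e2;Parent=gX.t1",
    "chr1\tsrc\tgene\t8001\t9000\t.\t-\t.\tID=gY"
  ), path)
  gm <- read_gff_genes(path)
  gx <- gm[gm$gene_id == "gX", ]
  expect_equal(gx$length, 2000L)       # two 1-kb exons, not the 4-kb span
  expect_equal(gx$start, 1000L)        # 0-based
  expect_equal(gx$end, 5000L)
  gy <- gm[gm$gene_id == "gY", ]
  expect_equal(gy$transcript_id, "gY") # gene without mRNA children
  expect_equal(gy$strand, "-")
})

test_that("paired CDS FASTA parses the pair_id|gene header convention", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1|geneA", "ATGAAA", ">p1|geneB", "ATGAAG"), path)
  pairs <- read_pair_cds(path)
  expect_equal(pairs$gene_a, "geneA")
  expect_equal(pairs$cds_b, "ATGAAG")
  writeLines(c(">p1|geneA", "ATG"), path)
  expect_error(read_pair_cds(path), "exactly two")
})
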