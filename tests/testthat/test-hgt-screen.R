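test_that("mixed orthogroups require both kingdoms", {
  og <- data.frame(
    og_id = c(rep("pure", 5), rep("mixed", 6)),
    kingdom = c(rep("plant", 5), rep("plant", 4), rep("fungus_oomycete", 2))
  )
  expect_equal(flag_mixed_orthogroups(og), "mixed")
  expect_error(flag_mixed_orthogroups(og[0, ]), "empty")
  og$kingdom[1] <- "animal"
  expect_error(flag_mixed_orthogroups(og), "kingdom label")
})

test_that("a planted nested foreign tip is called with the right direction", {
  ## ((plant1, fungusA)95, fungusB) inside a larger fungal clade
  txt <- "(((plant1:1,fungusA:1)95:1,fungusB:1)99:1,(fungusC:1,fungusD:2)90:3)98;"
  tree <- ape::read.tree(text = txt)
  kingdoms <- c(plant1 = "plant", fungusA = "fungus_oomycete",
                fungusB = "fungus_oomycete", fungusC = "fungus_oomycete",
                fungusD = "fungus_oomycete")
  calls <- detect_nested_foreign(tree, kingdoms, support_min = 70)
  high <- calls[calls$confidence == "high", ]
  expect_equal(high$gene_id, "plant1")
  expect_equal(high$direction, "fungi_to_plant")
  ## the same topology with support 40 on the enclosing splits: no call
  txt40 <- gsub("95|99|90|98", "40", txt)
  tree40 <- ape::read.tree(text = txt40)
  calls40 <- detect_nested_foreign(tree40, kingdoms, support_min = 70)
  expect_equal(nrow(calls40[calls40$confidence == "high", ]), 0L)
})

test_that("reciprocally monophyletic kingdoms yield no calls", {
  sim <- simulate_gene_tree_with_hgt(12, 12, n_transfers = 0, seed = 2)
  calls <- detect_nested_foreign(sim$tree, sim$kingdoms)
  expect_equal(nrow(calls), 0L)
  expect_error(
    detect_nested_foreign(sim$tree, sim$kingdoms[-1]),
    "unlabeled tip"
  )
})

test_that("planted transfers are recovered; support gates apply", {
  for (s in 1:10) {
    sim <- simulate_gene_tree_with_hgt(14, 14, n_transfers = 1,
                                       support = 100, seed = s)
    calls <- detect_nested_foreign(sim$tree, sim$kingdoms)
    high <- calls[calls$confidence == "high", ]
    expect_equal(high$gene_id, sim$truth$gene_id)
    expect_equal(high$direction, sim$truth$direction)
  }
  low <- simulate_gene_tree_with_hgt(14, 14, n_transfers = 1,
                                     support = 40, seed = 3)
  calls <- detect_nested_foreign(low$tree, low$kingdoms, support_min = 70)
  expect_equal(nrow(calls[calls$confidence == "high", ]), 0L)
})

test_that("calls are invariant to tip rotation and to input rooting", {
  sim <- simulate_gene_tree_with_hgt(12, 16, n_transfers = 1,
                                     support = 100, seed = 8)
  ref <- detect_nested_foreign(sim$tree, sim$kingdoms)
  ref_high <- ref[ref$confidence == "high", c("gene_id", "direction")]
  ## rotate every internal node: same calls
  rot <- sim$tree
  for (nd in (length(rot$tip.label) + 1):(length(rot$tip.label) + rot$Nnode)) {
    rot <- ape::rotate(rot, nd)
  }
  got <- detect_nested_foreign(rot, sim$kingdoms)
  got_high <- got[got$confidence == "high", c("gene_id", "direction")]
  expect_equal(got_high[order(got_high$gene_id), ],
               ref_high[order(ref_high$gene_id), ], ignore_attr = TRUE)
  ## reroot on several fungal tips: same calls
  fungi <- grep("^fungus", sim$tree$tip.label, value = TRUE)
  resident <- setdiff(fungi, sim$truth$gene_id)
  for (tip in resident[1:3]) {
    rr <- ape::root(ape::unroot(sim$tree), outgroup = tip,
                    resolve.root = TRUE, edgelabel = TRUE)
    got <- detect_nested_foreign(rr, sim$kingdoms)
    got_high <- got[got$confidence == "high", c("gene_id", "direction")]
    expect_equal(got_high[order(got_high$gene_id), ],
                 ref_high[order(ref_high$gene_id), ], ignore_attr = TRUE)
  }
})

test_that("top-hit corroboration applies the majority rule over top n", {
  hits <- data.frame(
    subject_kingdom = c(rep("fungus_oomycete", 8), rep("plant", 4)),
    bitscore = seq(120, 10, length.out = 12)
  )
  expect_true(tophit_corroborate(hits, "fungus_oomycete"))
  hits2 <- data.frame(
    subject_kingdom = c(rep("fungus_oomycete", 2), rep("plant", 8)),
    bitscore = seq(120, 10, length.out = 10)
  )
  expect_false(tophit_corroborate(hits2, "fungus_oomycete"))
  expect_false(tophit_corroborate(hits2[0, ], "fungus_oomycete"))
  ## exactly half does not pass the strict majority
  hits3 <- data.frame(subject_kingdom = rep(c("plant", "fungus_oomycete"), 5),
                      bitscore = 10:1)
  expect_false(tophit_corroborate(hits3, "fungus_oomycete"))
})
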