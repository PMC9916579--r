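## Builds a complete synthetic input bundle on disk for pipeline tests.
make_input_bundle <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  meta <- data.frame(
    species_id = c("spA", "spB", "spC", "spD"),
    category = c("Fabids", "Asterids", "Bryophyta", "Chlorophyta")
  )
  write_tsv_file(meta, p("species.tsv"))

  hits <- simulate_domain_hits(40, seed = seed)
  write_domain_hits(hits$hits, p("hits.tsv"))
  write_tsv_file(
    data.frame(protein_id = hits$truth$protein_id,
               species_id = rep(meta$species_id, 10)),
    p("proteins.tsv")
  )

  og <- data.frame(
    og_id = rep(sprintf("OG%02d", 1:6), each = 4),
    species_id = rep(meta$species_id, 6),
    gene_id = paste0("g", 1:24)
  )
  write_orthogroups(og, p("orthogroups.tsv"))

  fasta <- character(0)
  for (i in 1:4) {
    cp <- simulate_codon_pair(0.5, 0.3, 150, seed = seed + i)
    fasta <- c(fasta, sprintf(">pair%d|gA%d", i, i), cp$cds_a,
               sprintf(">pair%d|gB%d", i, i), cp$cds_b)
  }
  writeLines(fasta, p("pairs.fa"))

  ex <- simulate_expression(n_pairs = 4, seed = seed)
  genes <- c(rbind(sprintf("gA%d", 1:4), sprintf("gB%d", 1:4)))
  rownames(ex$counts) <- genes
  names(ex$gene_lengths) <- genes
  write_tsv_file(
    data.frame(gene_id = rownames(ex$counts), ex$counts, check.names = FALSE),
    p("counts.tsv")
  )
  write_tsv_file(ex$lib_meta, p("libs.tsv"))
  write_tsv_file(
    data.frame(gene_id = names(ex$gene_lengths),
               length = unname(ex$gene_lengths)),
    p("lengths.tsv")
  )

  hgt <- simulate_gene_tree_with_hgt(10, 10, 1, 100, seed = seed)
  ape::write.tree(hgt$tree, p("tree.nwk"))
  write_tsv_file(
    data.frame(gene_id = names(hgt$kingdoms),
               kingdom = unname(hgt$kingdoms)),
    p("kingdoms.tsv")
  )

  te <- simulate_te_annotation(peaks_my = 0.5, n_per_peak = 50, seed = seed)
  write_te_gff(te$te, p("te.gff3"))
  writeLines(c(
    "##gff-version 3",
    "ltr_contig\tsyn\tgene\t6001\t8000\t.\t+\t.\tID=geneX",
    "ltr_contig\tsyn\tmRNA\t6001\t8000\t.\t+\t.\tID=geneX.t1;Parent=geneX",
    "ltr_contig\tsyn\texon\t6001\t7000\t.\t+\t.\tID=e1;Parent=geneX.t1"
  ), p("genes.gff3"))
  write_tsv_file(data.frame(contig_id = "ltr_contig", length = 500000),
                 p("contigs.tsv"))

  cfg <- default_config()
  cfg$species_tsv <- p("species.tsv")
  cfg$hits_tsv <- p("hits.tsv")
  cfg$proteins_tsv <- p("proteins.tsv")
  cfg$orthogroups_tsv <- p("orthogroups.tsv")
  cfg$pairs_fasta <- p("pairs.fa")
  cfg$counts_tsv <- p("counts.tsv")
  cfg$libs_tsv <- p("libs.tsv")
  cfg$lengths_tsv <- p("lengths.tsv")
  cfg$tree_nwk <- p("tree.nwk")
  cfg$kingdoms_tsv <- p("kingdoms.tsv")
  cfg$te_gff <- p("te.gff3")
  cfg$genes_gff <- p("genes.gff3")
  cfg$contigs_tsv <- p("contigs.tsv")
  cfg$outdir <- p("out")
  cfg$seed <- seed
  cfg
}
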