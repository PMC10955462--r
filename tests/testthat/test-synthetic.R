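test_that("the synthetic gene model matches its advertised structure", {
  g <- test_genome()
  cypt <- g$models[["CYP^T"]]
  widths <- cypt$exons$end - cypt$exons$start
  expect_equal(widths[1], 286)
  expect_equal(widths[2], 227)
  expect_equal(length(widths), 5)
  expect_equal(sum(widths) %% 3, 0)
  # CDS translates cleanly: one terminal stop, no internal stop
  aa <- slocus:::translate_cds(g$cds[["CYP^T"]])
  expect_equal(aa[length(aa)], "*")
  expect_false(any(aa[-length(aa)] == "*"))
  # promoter is the 3 kb upstream of exon 1, motifs inside it
  expect_equal(cypt$promoter$end - cypt$promoter$start, 3000)
  expect_true(all(cypt$motifs$start >= cypt$promoter$start &
                    cypt$motifs$end <= cypt$promoter$end))
  # nine genes over two contigs
  expect_equal(length(g$models), 9)
  expect_setequal(unique(c(g$slocus_coding$chrom, g$genome_coding$chrom)),
                  c("Slocus", "Autosome"))
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(make_gene_model(seed = 3)$sequences,
                   make_gene_model(seed = 3)$sequences)
  expect_false(identical(make_gene_model(seed = 3)$sequences,
                         make_gene_model(seed = 4)$sequences))
  coh <- simulate_cohort(cohort_preset("en4t"))
  g <- test_genome()
  expect_identical(simulate_depth(coh, g, seed = 6),
                   simulate_depth(coh, g, seed = 6))
  groups <- tibble::tibble(individual = c("a", "b"), group = "x")
  expect_identical(
    simulate_genotype_matrix(groups, c(x = 0.01), n_sites = 500, seed = 2),
    simulate_genotype_matrix(groups, c(x = 0.01), n_sites = 500, seed = 2))
})

test_that("allele specs plant the catalogued mutations with truth labels", {
  g <- test_genome()
  s2 <- cypt_allele_spec("CYP^T-2", g)
  expect_equal(s2$events$expected_class, "stop_gain")
  s6 <- cypt_allele_spec("CYP^T-6", g)
  expect_equal(nchar(s6$events$ref) - nchar(s6$events$alt), 8)
  expect_equal(s6$events$expected_class, "frameshift")
  s8 <- cypt_allele_spec("CYP^T-8", g)
  expect_equal(s8$events$end - s8$events$start, 2150)
  exon1 <- g$models[["CYP^T"]]$exons[1, ]
  expect_true(s8$events$start <= exon1$start && s8$events$end >= exon1$end)

  # applying the allele mutates the haplotype accordingly
  mut2 <- apply_allele(g, s2)
  expect_equal(nchar(mut2$sequence), nchar(g$sequences[["Slocus"]]))
  expect_equal(substr(mut2$sequence, s2$events$pos, s2$events$pos),
               s2$events$alt)
  mut8 <- apply_allele(g, s8)
  expect_equal(nchar(g$sequences[["Slocus"]]) - nchar(mut8$sequence), 2150)
  expect_error(cypt_allele_spec("CYP^T-9", g), "unknown")
})

test_that("cohort presets reproduce the surveyed composition", {
  full <- simulate_cohort(cohort_preset("full"))
  expect_equal(nrow(full), 105)
  expect_equal(sum(full$phenotype == "thrum"), 37)
  expect_equal(sum(full$phenotype == "pin"), 37)
  expect_equal(sum(full$phenotype == "homostyle"), 31)
  # 10 of 31 homostyles haploid (S*/0)
  expect_equal(sum(full$genotype == "S*/0"), 10)
  expect_equal(sum(full$genotype == "S*/S*"), 21)
  # three diploid thrums: two S/S and one S/S*
  expect_equal(sum(full$genotype == "S/S"), 2)
  expect_equal(sum(full$genotype == "S/S*"), 1)
  expect_equal(sum(full$genotype == "S/0"), 34)
  # EN4-T homostyles: 4 haploid, 6 diploid, alleles 8 x -6 + 2 x -2
  en4 <- full[full$population == "EN4-T" & full$phenotype == "homostyle", ]
  expect_equal(sum(en4$genotype == "S*/0"), 4)
  expect_equal(sum(en4$cypt_allele == "CYP^T-6"), 8)
  # genotypes always consistent with phenotypes
  expect_true(all(full$genotype[full$phenotype == "pin"] == "0/0"))
  expect_true(all(full$genotype[full$phenotype == "homostyle"] %in%
                    c("S*/0", "S*/S*")))
})

test_that("multinomial cohorts follow the supplied model state", {
  all_s <- simulate_cohort(state = crosby_state(0, 0, 0, 1), n = 25, seed = 9)
  expect_equal(nrow(all_s), 25)
  expect_true(all(all_s$genotype == "S*/S*"))
  mixed <- simulate_cohort(state = crosby_state(0.25, 0.25, 0.25, 0.25),
                           n = 400, seed = 10)
  expect_equal(nrow(mixed), 400)
  expect_gt(min(table(mixed$genotype)), 50)
})

test_that("depth tracks encode copy number and structural deletions", {
  g <- test_genome()
  coh <- simulate_cohort(cohort_preset("en6m"))
  dp <- simulate_depth(coh, g, lambda = 19, seed = 12)
  span <- slocus:::cypt_deletion_span(g)
  in_del <- dp$chrom == "Slocus" & dp$pos > span$start & dp$pos <= span$end
  for (id in coh$individual) {
    expect_true(all(dp[[id]][in_del] == 0))
  }
  # outside the deletion, diploid homostyles have full depth
  out_del <- dp$chrom == "Slocus" & !in_del
  expect_equal(mean(dp[[coh$individual[1]]][out_del]), 19, tolerance = 0.15)
})

test_that("written VCFs round-trip through vcfR", {
  groups <- tibble::tibble(individual = c("a", "b", "c"), group = "g")
  gm <- simulate_genotype_matrix(groups, c(g = 0.02), n_sites = 300,
                                 missing_rate = 0.1, seed = 14)
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf_genotypes(path)
  expect_equal(back$pos, gm$pos)
  expect_equal(back$a, gm$a)
  expect_equal(back$c, gm$c)
  # FASTA and BED writers emit parseable files
  g <- test_genome()
  fa <- tempfile(fileext = ".fa")
  write_fasta(g$sequences, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(seqs[["Slocus"]]), g$sequences[["Slocus"]])
  bed <- tempfile(fileext = ".bed")
  write_bed(g$slocus_coding, bed)
  expect_equal(read_bed(bed)$start, g$slocus_coding$start)
})
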