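test_that("degeneracy classes follow the codon table", {
  # GGG (Gly): third position 4-fold; ATG (Met): all 0-fold;
  # ATT (Ile): third position 3-fold -> other
  tr <- annotate_degeneracy("ATGGGGATTTAA")
  expect_equal(tr$class[tr$cds_pos %in% 1:3], rep("0-fold", 3))
  expect_equal(tr$class[tr$cds_pos == 6], "4-fold")
  expect_equal(tr$class[tr$cds_pos == 9], "other")
  expect_equal(nrow(tr), 12)
})

test_that("degeneracy totals partition the CDS and match brute force", {
  g <- test_genome()
  cds <- g$cds[["CYP^T"]]
  tr <- annotate_degeneracy(cds, model = g$models[["CYP^T"]])
  expect_equal(nrow(tr), nchar(cds))
  expect_setequal(unique(tr$class), c("0-fold", "4-fold", "other"))
  # brute force via whole-CDS translation on a sample of positions
  set.seed(2)
  for (cp in sample(which(tr$cds_pos <= nchar(cds) - 3), 60)) {
    ref_base <- substr(cds, cp, cp)
    changed <- vapply(setdiff(c("A", "C", "G", "T"), ref_base),
                      function(b) oracle_snv_class(cds, cp, b) != "synonymous",
                      logical(1))
    expected <- if (all(changed)) "0-fold" else if (!any(changed)) "4-fold"
                else "other"
    expect_equal(tr$class[cp], expected, info = paste("cds_pos", cp))
  }
  # genomic coordinates round-trip through the gene model
  expect_equal(slocus:::genomic_to_cds(g$models[["CYP^T"]], tr$pos),
               tr$cds_pos)
})

test_that("pi matches the hand-computed two-individual example", {
  # 2 homozygous diploids differing at 1 of 100 callable sites:
  # diffs = 2*2 = 4, comparisons per site = C(4,2) = 6
  gm <- tibble::tibble(chrom = "c", pos = 1:100, ref = "A",
                       alt = c("T", rep(NA, 99)),
                       i1 = c("1/1", rep("0/0", 99)),
                       i2 = rep("0/0", 100))
  out <- pi_from_genotypes(gm)
  expect_equal(out$pi, (4 / 6) / 100)
  expect_equal(out$diffs, 4)
  expect_equal(out$comparisons, 600)
})

test_that("identical individuals give pi = 0 and empty groups error", {
  gm <- tibble::tibble(chrom = "c", pos = 1:10, ref = "A", alt = NA,
                       i1 = "0/0", i2 = "0/0")
  expect_equal(pi_from_genotypes(gm)$pi, 0)
  expect_error(pi_from_genotypes(gm, individuals = character()), "non-empty")
})

test_that("pi equals the naive pairwise-haplotype average under missing data", {
  set.seed(31)
  for (rep in 1:12) {
    n_sites <- 20; n_ind <- 8
    gm <- tibble::tibble(chrom = "c", pos = seq_len(n_sites), ref = "A",
                         alt = "T")
    for (i in seq_len(n_ind)) {
      g <- sample(c("0/0", "0/1", "1/1", NA), n_sites, replace = TRUE,
                  prob = c(0.4, 0.25, 0.2, 0.15))
      gm[[paste0("i", i)]] <- g
    }
    inds <- paste0("i", seq_len(n_ind))
    mine <- suppressWarnings(pi_from_genotypes(gm, individuals = inds)$pi)
    ref <- oracle_pi(gm, inds)
    if (is.na(ref)) expect_true(is.na(mine))
    else expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("a site missing in half the group contributes only called alleles", {
  gm <- tibble::tibble(chrom = "c", pos = 1L, ref = "A", alt = "T",
                       i1 = "0/1", i2 = NA_character_)
  out <- pi_from_genotypes(gm)
  expect_equal(out$comparisons, 1)  # C(2,2): only i1's two alleles
  expect_equal(out$pi, 1)
})

test_that("haploid mode counts one allele per hemizygote", {
  gm <- tibble::tibble(chrom = "c", pos = 1:2, ref = "A", alt = "T",
                       h1 = c("1/1", "0/0"), h2 = c("0/0", "0/0"))
  dip <- pi_from_genotypes(gm)
  hap <- pi_from_genotypes(gm, haploid = c("h1", "h2"))
  expect_equal(dip$pi, (2 * 2 / choose(4, 2)) / 2)
  expect_equal(hap$pi, (1 * 1 / choose(2, 2)) / 2)
})

test_that("the estimator recovers the generator's per-site heterozygosity", {
  groups <- tibble::tibble(individual = paste0("d", 1:20), group = "out")
  for (theta in c(0.001, 0.005)) {
    gm <- simulate_genotype_matrix(groups, theta = c(out = theta),
                                   n_sites = 10000, seed = round(theta * 1e6))
    est <- pi_from_genotypes(gm)
    # Monte-Carlo SE of the mean per-site heterozygosity
    se <- sqrt(theta * 0.5 / 10000)
    expect_lt(abs(est$pi - theta), 3 * se + 1e-6)
  }
})

test_that("selfing groups show reduced diversity relative to outcrossers", {
  groups <- tibble::tibble(
    individual = c(paste0("o", 1:15), paste0("s", 1:15)),
    group = rep(c("outcrossing", "selfing"), each = 15))
  wins <- 0
  for (seed in 1:20) {
    gm <- simulate_genotype_matrix(
      groups, theta = c(outcrossing = 0.003, selfing = 0.0005),
      n_sites = 5000, selfing_groups = "selfing", seed = seed)
    po <- pi_from_genotypes(gm, individuals = paste0("o", 1:15))$pi
    ps <- pi_from_genotypes(gm, individuals = paste0("s", 1:15))$pi
    wins <- wins + (po > ps)
  }
  expect_gte(wins, 19)
})

test_that("pi ratio handles zero synonymous diversity as NA", {
  expect_equal(pi_ratio(0.0007, 0.0026), 0.0007 / 0.0026)
  expect_true(is.na(pi_ratio(0.0015, 0)))
  expect_equal(pi_ratio(0, 0.001), 0)
  expect_error(pi_ratio(-0.1, 0.2), ">= 0")
})

test_that("group summaries average per statistic with SE and exclusions", {
  est <- tibble::tibble(
    gene = c("CYP^T", "GLO^T", "CCM^T", "KFB^T", "PUM^T"),
    group = "thrum", n = 37,
    pi_s = c(0.0026, 0, 0.0018, 0.0004, 0.0001),
    pi_n = c(0.0007, 0.0015, 0.0016, 0.0007, 0.0011))
  est$ratio <- pi_ratio(est$pi_n, est$pi_s)
  out <- summarize_gene_groups(est, exclude_genes = "PUM^T")
  all_s <- out[out$block == "all genes" & out$statistic == "pi_s", ]
  expect_equal(round(all_s$mean, 4), 0.0010)
  expect_equal(all_s$n_genes, 5L)
  # ratio averages skip NA entries (GLO^T has pi_s = 0)
  all_r <- out[out$block == "all genes" & out$statistic == "ratio", ]
  expect_equal(all_r$n_genes, 4L)
  # exclusion block recomputes over the remaining genes
  ex_s <- out[grepl("excluding", out$block) & out$statistic == "pi_s", ]
  expect_equal(ex_s$mean, mean(est$pi_s[est$gene != "PUM^T"]))
  # single-value cells have undefined SE
  single <- summarize_gene_groups(est[1, ])
  expect_true(all(is.na(single$se)))
})

test_that("the per-gene table reproduces the selfing contrast end to end", {
  g <- test_genome()
  groups <- tibble::tibble(
    individual = c(paste0("t", 1:12), paste0("h", 1:10)),
    group = rep(c("thrum", "homostyle"), c(12, 10)))
  cls <- NULL
  gm <- NULL
  offset <- 0L
  for (gene in c("CYP^T", "GLO^T")) {
    cds <- g$cds[[gene]]
    tr <- annotate_degeneracy(cds, model = g$models[[gene]])
    tr$gene <- gene
    cls <- dplyr::bind_rows(cls, tr[, c("chrom", "pos", "class", "gene")])
    sub <- simulate_genotype_matrix(
      groups, theta = c(thrum = 0.01, homostyle = 0.0005),
      n_sites = nchar(cds), selfing_groups = "homostyle",
      chrom = "Slocus", seed = offset + 13)
    sub$pos <- sort(tr$pos)
    gm <- dplyr::bind_rows(gm, sub)
    offset <- offset + 1L
  }
  tab <- diversity_table(gm, cls, groups)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("pi_s", "pi_n", "ratio") %in% names(tab)))
  # whole-gene diversity shows the selfing contrast for every gene
  for (gene in c("CYP^T", "GLO^T")) {
    sites <- cls[cls$gene == gene, c("chrom", "pos")]
    pt <- pi_from_genotypes(gm, sites = sites,
                            individuals = paste0("t", 1:12))$pi
    ph <- pi_from_genotypes(gm, sites = sites,
                            individuals = paste0("h", 1:10))$pi
    expect_lt(ph, pt)
  }
})
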