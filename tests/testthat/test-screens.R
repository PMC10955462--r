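toy_matrix <- function(hom_gts, thr_gts, pos = 100L) {
  n_h <- length(hom_gts); n_t <- length(thr_gts)
  gm <- tibble::tibble(chrom = "Slocus", pos = pos, ref = "A", alt = "T")
  for (i in seq_len(n_h)) gm[[paste0("hom", i)]] <- hom_gts[i]
  for (i in seq_len(n_t)) gm[[paste0("thr", i)]] <- thr_gts[i]
  gm
}
toy_groups <- function(n_h, n_t) {
  tibble::tibble(individual = c(paste0("hom", seq_len(n_h)),
                                paste0("thr", seq_len(n_t))),
                 group = rep(c("homostyle", "thrum"), c(n_h, n_t)))
}

test_that("homostyle-specific SNPs are reported with carrier counts and fixation", {
  # all homostyles alt, all thrums ref -> fixed
  out <- screen_group_specific_snps(
    toy_matrix(rep("1/1", 4), rep("0/0", 4)), toy_groups(4, 4))
  expect_equal(nrow(out), 1)
  expect_true(out$fixed)
  expect_equal(out$carriers, 4L)

  # 8 of 31 homostyle carriers, 0 thrums -> reported, not fixed
  out <- screen_group_specific_snps(
    toy_matrix(rep(c("1/1", "0/0"), c(8, 23)), rep("0/0", 37)),
    toy_groups(31, 37))
  expect_false(out$fixed)
  expect_equal(out$carriers, 8L)

  # a single thrum carrier removes the site from the report
  out <- screen_group_specific_snps(
    toy_matrix(rep("1/1", 4), c("0/1", rep("0/0", 3))), toy_groups(4, 4))
  expect_equal(nrow(out), 0)

  # missing homostyle calls do not block fixation among called individuals
  out <- screen_group_specific_snps(
    toy_matrix(c("1/1", "1/1", NA), rep("0/0", 3)), toy_groups(3, 3))
  expect_true(out$fixed)
  expect_equal(out$n_called, 2L)

  expect_error(
    screen_group_specific_snps(toy_matrix("1/1", "0/0"),
                               tibble::tibble(individual = "hom1",
                                              group = "homostyle")),
    "non-empty")
})

test_that("zero-depth run detection matches a naive scan", {
  # spec example: depth 5,0,0,0,7 with min_length 2 -> one run of 3
  dp <- tibble::tibble(chrom = "c", pos = 1:5, ind = c(5, 0, 0, 0, 7))
  region <- tibble::tibble(chrom = "c", start = 0L, end = 5L)
  out <- detect_zero_depth_runs(dp, "ind", region, min_length = 2)
  expect_equal(nrow(out), 1)
  expect_equal(out$length, 3L)
  expect_equal(c(out$start, out$end), c(1L, 4L))

  # all-positive track yields nothing
  dp$ind <- 5
  expect_equal(nrow(detect_zero_depth_runs(dp, "ind", region, 1)), 0)

  # random binary masks against the oracle
  set.seed(9)
  for (i in 1:15) {
    n <- 200L
    d <- ifelse(stats::runif(n) < 0.3, 0, stats::rpois(n, 10) + 1)
    dp <- tibble::tibble(chrom = "c", pos = seq_len(n), ind = d)
    region <- tibble::tibble(chrom = "c", start = 0L, end = n)
    min_len <- sample(1:5, 1)
    out <- detect_zero_depth_runs(dp, "ind", region, min_len)
    ref <- oracle_zero_runs(d, min_len)
    expect_equal(nrow(out), length(ref))
    if (length(ref) > 0) {
      expect_equal(out$start + 1L,
                   vapply(ref, function(r) as.integer(r[1]), integer(1)))
      expect_equal(out$end,
                   vapply(ref, function(r) as.integer(r[2]), integer(1)))
    }
  }
})

test_that("read-pair orientation tallies separate the three signals", {
  region <- tibble::tibble(chrom = "Slocus", start = 0L, end = 10000L)
  pairs <- simulate_read_pairs(100, 10, 5, region, seed = 2)
  out <- flag_discordant_pairs(pairs, region)
  expect_equal(out$normal_count, 100)
  expect_equal(out$same_orientation_count, 10)
  expect_equal(out$cross_contig_count, 5)
  expect_equal(out$unresolvable_count, 0)

  # incomplete mate information is reported separately
  pairs$contig2[1] <- NA
  out <- flag_discordant_pairs(pairs, region)
  expect_equal(out$unresolvable_count, 1)
  expect_equal(out$normal_count, 99)
})

test_that("allele classification maps signatures to the catalogue", {
  g <- test_genome()
  model <- g$models[["CYP^T"]]
  no_cons <- tibble::tibble(class = character(), exon = integer())
  no_dels <- tibble::tibble(start = integer(), end = integer())

  expect_equal(classify_cypt_allele(no_cons, no_dels, model)$allele, "CYP^T-1")

  stop2 <- tibble::tibble(class = "stop_gain", exon = 2L)
  out <- classify_cypt_allele(stop2, no_dels, model)
  expect_equal(out$allele, "CYP^T-2")
  expect_equal(out$functional_status, "disrupted")

  fs1 <- tibble::tibble(class = "frameshift", exon = 1L)
  expect_equal(classify_cypt_allele(fs1, no_dels, model)$allele, "CYP^T-6")

  del1 <- tibble::tibble(start = model$exons$start[1] - 1600L,
                         end = model$exons$start[1] + 550L)
  expect_equal(classify_cypt_allele(no_cons, del1, model)$allele, "CYP^T-8")

  # conflicting signatures are labelled novel, never coerced
  both <- dplyr::bind_rows(stop2, fs1)
  out <- classify_cypt_allele(both, no_dels, model)
  expect_equal(out$allele, "novel")
  expect_equal(out$functional_status, "disrupted")
})

test_that("the full cohort screen recovers every planted allele", {
  g <- test_genome()
  coh <- simulate_cohort(cohort_preset("full"))
  vr <- simulate_cypt_variants(coh, g, seed = 3)
  dp <- simulate_depth(coh, g, seed = 4)
  sc <- screen_cypt_cohort(g, coh, vr, dp)
  truth <- coh

  hom <- sc[sc$phenotype == "homostyle", ]
  expect_true(all(hom$cypt_status == "disrupted"))
  expect_equal(hom$allele,
               truth$cypt_allele[match(hom$individual, truth$individual)])

  thr <- sc[sc$phenotype == "thrum", ]
  shet <- truth$individual[truth$genotype == "S/S*"]
  expect_equal(thr$cypt_status[thr$individual %in% shet],
               "heterozygous_functional_disrupted")
  expect_true(all(thr$cypt_status[!thr$individual %in% shet] == "functional"))

  # no intronic or promoter SNP is fixed across all 31 homostyles
  model <- g$models[["CYP^T"]]
  noncoding <- dplyr::bind_rows(model$introns, model$promoter, model$motifs)
  snps <- screen_group_specific_snps(vr$matrix, vr$groups,
                                     regions = noncoding)
  expect_gt(nrow(snps), 0)          # homostyle-specific SNPs do exist
  expect_false(any(snps$fixed & snps$n_called == 31))
})
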