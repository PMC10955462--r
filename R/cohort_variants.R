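# CYP^T variant matrix for a simulated cohort, and the end-to-end screen
# that recovers each individual's allele from variants plus depth.

#' Simulate the CYP^T variant matrix of a cohort
#'
#' Emits a genotype matrix over the CYP^T region for all S-locus carriers
#' (thrums and homostyles; pins have no S-locus and are absent from the
#' call set). Hemizygous carriers appear as diploid homozygous calls, as
#' they do in a joint diploid call set. Planted variants: the exon-2
#' stop-gain SNV (homozygous in `CYP^T-2` homostyles, heterozygous in the
#' `S/S*` thrum), the 8-bp exon-1 frameshift deletion in `CYP^T-6`
#' carriers, allele-tag intron SNPs private to the `CYP^T-6` and `CYP^T-8`
#' carrier groups, and neutral intron SNPs segregating in thrums. No SNP
#' is fixed across all homostyles.
#'
#' @param cohort A [simulate_cohort()] truth table.
#' @param genome A [make_gene_model()] result.
#' @param n_background Number of neutral thrum-segregating intron SNPs.
#' @param seed Integer seed.
#' @return A list: `matrix` (genotype-matrix tibble), `groups`
#'   (`individual`, `group` for thrums and homostyles).
#' @export
simulate_cypt_variants <- function(cohort, genome, n_background = 12,
                                   seed = 1) {
  model <- genome$models[["CYP^T"]]
  seqs <- genome$sequences[["Slocus"]]
  carriers <- cohort[cohort$phenotype != "pin", ]
  ids <- carriers$individual

  spec2 <- cypt_allele_spec("CYP^T-2", genome)$events
  spec6 <- cypt_allele_spec("CYP^T-6", genome)$events

  has_allele <- function(a) {
    vapply(carriers$cypt_allele, function(x) {
      !is.na(x) && a %in% strsplit(x, "/", fixed = TRUE)[[1]]
    }, logical(1))
  }
  het_carrier <- grepl("/", carriers$cypt_allele, fixed = TRUE)

  gt_row <- function(carrier_mask, het_mask = rep(FALSE, length(ids))) {
    g <- rep("0/0", length(ids))
    g[carrier_mask] <- "1/1"
    g[carrier_mask & het_mask] <- "0/1"
    g
  }
  intron_pos <- function(intron_i, frac) {
    iv <- model$introns[intron_i, ]
    as.integer(iv$start + round(frac * (iv$end - iv$start)))
  }
  base_at <- function(pos) substr(seqs, pos, pos)
  other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

  rows <- list(
    list(pos = spec2$pos[1], ref = spec2$ref[1], alt = spec2$alt[1],
         gt = gt_row(has_allele("CYP^T-2"), het_carrier)),
    list(pos = spec6$pos[1], ref = spec6$ref[1], alt = spec6$alt[1],
         gt = gt_row(has_allele("CYP^T-6"))),
    # allele-tag intron SNPs (shared within a carrier group, absent in thrums)
    list(pos = intron_pos(1L, 0.6), gt = gt_row(has_allele("CYP^T-6"))),
    list(pos = intron_pos(4L, 0.5), gt = gt_row(has_allele("CYP^T-8")))
  )
  rows <- purrr::map(rows, function(r) {
    if (is.null(r$ref)) {
      r$ref <- base_at(r$pos)
      r$alt <- other_base(r$ref)
    }
    r
  })

  # neutral intron SNPs segregating in thrums (some also in homostyles, so
  # they are not homostyle-specific)
  is_thrum <- carriers$phenotype == "thrum"
  bg <- with_seed(seed, {
    purrr::map(seq_len(n_background), function(k) {
      pos <- intron_pos(sample.int(4, 1), stats::runif(1, 0.05, 0.95))
      carrier <- rep(FALSE, length(ids))
      carrier[is_thrum] <- stats::runif(sum(is_thrum)) < 0.3
      if (k %% 3 == 0) {
        carrier[!is_thrum] <- stats::runif(sum(!is_thrum)) < 0.2
      }
      list(pos = pos, ref = base_at(pos), alt = other_base(base_at(pos)),
           gt = gt_row(carrier))
    })
  })
  rows <- c(rows, bg)

  gm <- purrr::map_dfr(rows, function(r) {
    out <- tibble(chrom = model$chrom, pos = r$pos, ref = r$ref, alt = r$alt)
    dplyr::bind_cols(out, stats::setNames(as.list(r$gt), ids))
  }) |>
    dplyr::arrange(.data$pos) |>
    dplyr::distinct(.data$pos, .keep_all = TRUE)

  list(matrix = gm,
       groups = tibble(individual = ids,
                       group = dplyr::if_else(is_thrum, "thrum", "homostyle")))
}

#' End-to-end CYP^T screen over a simulated cohort
#'
#' For every S-locus carrier: annotates the coding consequence of their
#' alternate-allele variants, scans their depth track for zero-depth
#' deletions over the CYP^T region, classifies the allele, and derives the
#' CYP^T functional status (heterozygous carriers of a single disruptive
#' event are `heterozygous_functional_disrupted`). Pins are reported with
#' status `absent`.
#'
#' @param genome A [make_gene_model()] result.
#' @param cohort A [simulate_cohort()] truth table.
#' @param variants Output of [simulate_cypt_variants()] (or a compatible
#'   genotype matrix list).
#' @param depth Depth track from [simulate_depth()].
#' @param min_deletion_length Minimum structural-deletion length (bp).
#' @return A tibble: `individual`, `phenotype`, `allele`, `cypt_status`,
#'   `evidence`.
#' @export
screen_cypt_cohort <- function(genome, cohort, variants, depth,
                               min_deletion_length = 50) {
  model <- genome$models[["CYP^T"]]
  cds <- genome$cds[["CYP^T"]]
  gm <- variants$matrix
  region <- tibble(chrom = model$chrom,
                   start = min(model$promoter$start),
                   end = max(model$exons$end) + 200L)
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    ind <- cohort[i, ]
    if (ind$phenotype == "pin") {
      return(tibble(individual = ind$individual, phenotype = "pin",
                    allele = NA_character_, cypt_status = "absent",
                    evidence = "no S-locus"))
    }
    g <- gm[[ind$individual]]
    has_alt <- !is.na(g) & g %in% c("0/1", "1/0", "1/1")
    cons <- if (any(has_alt)) {
      annotate_cds_consequence(model, cds, gm[has_alt, c("chrom", "pos", "ref", "alt")])
    } else {
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character(), class = character(), exon = integer(),
             protein_change = character())
    }
    dels <- detect_zero_depth_runs(depth, ind$individual, region,
                                   min_length = min_deletion_length,
                                   model = model)
    call <- classify_cypt_allele(cons, dels, model)
    status <- call$functional_status
    if (status == "disrupted" && nrow(cons) > 0) {
      disruptive <- cons$class %in% c("stop_gain", "frameshift")
      if (any(disruptive) && nrow(dels) == 0 &&
          all(g[has_alt][disruptive] %in% c("0/1", "1/0"))) {
        status <- "heterozygous_functional_disrupted"
      }
    }
    tibble(individual = ind$individual, phenotype = ind$phenotype,
           allele = call$allele, cypt_status = status,
           evidence = call$evidence)
  })
}
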