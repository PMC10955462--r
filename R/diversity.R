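# Degeneracy annotation and missing-data-aware nucleotide diversity
# (pi at 4-fold / synonymous and 0-fold / non-synonymous sites), following
# the summation used by pixy: pi = sum(site differences) / sum(site
# comparisons) over non-missing allele pairs, with invariant-but-callable
# sites contributing comparisons only.

#' Annotate codon degeneracy along a CDS
#'
#' A CDS position is 4-fold degenerate when all three alternative
#' nucleotides preserve the encoded amino acid, 0-fold when all three
#' change it, and `other` otherwise (2- and 3-fold positions are excluded
#' from both diversity classes). Codons containing ambiguity characters are
#' classified `other` at all three positions.
#'
#' @param cds CDS string (length divisible by 3, no internal stop).
#' @param model Optional [gene_model()]; when supplied, genomic coordinates
#'   (`chrom`, `pos`) are added to the track.
#' @return A tibble with columns `cds_pos`, `codon`, `codon_pos`, `class`
#'   (`"0-fold"`, `"4-fold"`, `"other"`), plus `chrom`/`pos` when `model`
#'   is given.
#' @export
annotate_degeneracy <- function(cds, model = NULL) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) abort("CDS length must be divisible by 3")
  n_codon <- n %/% 3
  codons <- substring(cds, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- translate_codon(codons)
  if (any(aa[-n_codon] == "*", na.rm = TRUE)) {
    abort("CDS contains an internal stop codon")
  }
  bases <- c("A", "C", "G", "T")
  class_codon <- function(codon) {
    if (is.na(translate_codon(codon))) return(rep("other", 3))
    vapply(1:3, function(k) {
      ref_base <- substr(codon, k, k)
      alts <- setdiff(bases, ref_base)
      changed <- vapply(alts, function(b) {
        mut <- codon
        substr(mut, k, k) <- b
        translate_codon(mut) != translate_codon(codon)
      }, logical(1))
      if (all(changed)) "0-fold" else if (!any(changed)) "4-fold" else "other"
    }, character(1))
  }
  cls <- unlist(lapply(codons, class_codon), use.names = FALSE)
  out <- tibble(
    cds_pos = seq_len(n),
    codon = rep(codons, each = 3),
    codon_pos = rep.int(1:3, n_codon),
    class = cls)
  if (!is.null(model)) {
    out$chrom <- model$chrom
    out$pos <- cds_to_genomic(model, out$cds_pos)
  }
  out
}

# Per-site ref/alt allele counts from genotype strings. Hemizygous
# individuals may be listed in `haploid` to contribute one allele instead
# of two (optional haploid mode; default consumes calls as written).
allele_counts <- function(gm, individuals, haploid = character()) {
  geno <- as.matrix(gm[individuals])
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    out[g %in% "0/0"] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g %in% "1/1"] <- 2
    out[g %in% "0"] <- 0
    out[g %in% "1"] <- 1
    out
  }
  alt <- apply(geno, 2, count_alt)
  if (nrow(gm) == 1) alt <- matrix(alt, nrow = 1, dimnames = list(NULL, individuals))
  ploidy <- matrix(2, nrow = nrow(gm), ncol = length(individuals),
                   dimnames = list(NULL, individuals))
  ploidy[is.na(alt)] <- 0
  for (id in intersect(haploid, individuals)) {
    hap_called <- !is.na(alt[, id])
    ploidy[hap_called, id] <- 1
    # a hemizygote's diploid-style homozygous call carries one real allele
    alt[hap_called, id] <- as.numeric(alt[hap_called, id] > 0)
  }
  alt[is.na(alt)] <- 0
  list(c_alt = rowSums(alt), c_tot = rowSums(ploidy))
}

#' Nucleotide diversity from a genotype matrix
#'
#' Per site, with `c_ref` and `c_alt` alleles counted among non-missing
#' genotypes, the number of pairwise differences is `c_ref * c_alt` and the
#' number of pairwise comparisons is `choose(c_ref + c_alt, 2)`; the
#' aggregate estimate is the ratio of the two sums. Sites with fewer than
#' two called alleles contribute to neither sum. Invariant sites (alt `NA`
#' or `"."`, or no alternate alleles called) add comparisons only, which is
#' what distinguishes this estimator from SNP-only averages.
#'
#' @param genotypes Genotype-matrix tibble (`chrom`, `pos`, `ref`, `alt`,
#'   one genotype column per individual).
#' @param sites Optional tibble (`chrom`, `pos`) or logical/integer index
#'   restricting the summed sites (e.g. a 4-fold degeneracy track).
#' @param individuals Optional character vector naming the group; defaults
#'   to every genotype column.
#' @param haploid Individuals whose diploid-style homozygous calls should
#'   count a single allele (hemizygous S-locus carriers; optional mode).
#' @return A one-row tibble: `n` (individuals), `n_sites` (sites with >= 2
#'   called alleles), `diffs`, `comparisons`, `pi` (NA with a warning when
#'   no comparisons are available).
#' @export
pi_from_genotypes <- function(genotypes, sites = NULL, individuals = NULL,
                              haploid = character()) {
  gm <- as_tibble(genotypes)
  if (is.null(individuals)) {
    individuals <- setdiff(names(gm), c("chrom", "pos", "ref", "alt"))
  }
  if (length(individuals) == 0) abort("`individuals` must be non-empty")
  if (!is.null(sites)) {
    if (is.data.frame(sites)) {
      keep <- paste(gm$chrom, gm$pos) %in% paste(sites$chrom, sites$pos)
    } else {
      keep <- sites
    }
    gm <- gm[keep, , drop = FALSE]
  }
  if (nrow(gm) == 0) {
    warn("no sites to aggregate; pi undefined")
    return(tibble(n = length(individuals), n_sites = 0L, diffs = 0,
                  comparisons = 0, pi = NA_real_))
  }
  ac <- allele_counts(gm, individuals, haploid)
  c_alt <- ac$c_alt
  c_ref <- ac$c_tot - ac$c_alt
  informative <- ac$c_tot >= 2
  diffs <- sum(c_ref[informative] * c_alt[informative])
  comparisons <- sum(choose(ac$c_tot[informative], 2))
  pi <- if (comparisons == 0) {
    warn("no pairwise comparisons available; pi undefined")
    NA_real_
  } else diffs / comparisons
  tibble(n = length(individuals), n_sites = sum(informative),
         diffs = diffs, comparisons = comparisons, pi = pi)
}

#' Ratio of non-synonymous to synonymous diversity
#'
#' @param pi_n,pi_s Non-negative diversity estimates.
#' @return `pi_n / pi_s`, or `NA` when `pi_s` is zero (no synonymous
#'   variation, as for GLO^T in thrums).
#' @export
pi_ratio <- function(pi_n, pi_s) {
  if (any(c(pi_n, pi_s) < 0, na.rm = TRUE)) abort("pi values must be >= 0")
  dplyr::if_else(is.na(pi_s) | pi_s == 0, NA_real_, pi_n / pi_s)
}

#' Per-gene, per-group diversity table
#'
#' Computes `pi_s` (4-fold sites), `pi_n` (0-fold sites) and their ratio
#' for each gene and group, in the layout of the study's diversity table.
#'
#' @param genotypes Genotype-matrix tibble covering all genes.
#' @param site_classes Degeneracy track with columns `chrom`, `pos`,
#'   `class`, `gene` (from [annotate_degeneracy()] with a model, plus a
#'   `gene` label).
#' @param groups Tibble `individual`, `group`.
#' @param haploid Passed to [pi_from_genotypes()].
#' @return A tibble: `gene`, `group`, `n`, `pi_s`, `pi_n`, `ratio`.
#' @export
diversity_table <- function(genotypes, site_classes, groups,
                            haploid = character()) {
  combos <- tidyr::expand_grid(gene = unique(site_classes$gene),
                               group = unique(groups$group))
  purrr::pmap_dfr(combos, function(gene, group) {
    inds <- groups$individual[groups$group == group]
    cls <- site_classes[site_classes$gene == gene, ]
    est <- function(class_label) {
      sites <- cls[cls$class == class_label, c("chrom", "pos")]
      if (nrow(sites) == 0) return(NA_real_)
      suppressWarnings(
        pi_from_genotypes(genotypes, sites = sites, individuals = inds,
                          haploid = haploid)$pi)
    }
    pi_s <- est("4-fold"); pi_n <- est("0-fold")
    tibble(gene = gene, group = group, n = length(inds),
           pi_s = pi_s, pi_n = pi_n, ratio = pi_ratio(pi_n, pi_s))
  })
}

#' Mean and standard error of diversity statistics per group
#'
#' Arithmetic mean and SE of `pi_s`, `pi_n` and `ratio` across genes within
#' each group; `NA` ratios are excluded from the ratio averages. A second
#' block excluding listed genes (e.g. an outlier gene) can be requested.
#'
#' @param estimates Output of [diversity_table()].
#' @param exclude_genes Optional character vector of genes to drop in an
#'   additional `"excluding <genes>"` block.
#' @return A tibble: `group`, `block`, `statistic`, `mean`, `se`,
#'   `n_genes`. SE is `NA` for a single value.
#' @export
summarize_gene_groups <- function(estimates, exclude_genes = NULL) {
  one_block <- function(df, label) {
    df |>
      tidyr::pivot_longer(c("pi_s", "pi_n", "ratio"),
                          names_to = "statistic", values_to = "value") |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::group_by(.data$group, .data$statistic) |>
      dplyr::summarise(
        mean = mean(.data$value),
        se = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n())
             else NA_real_,
        n_genes = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(block = label, .after = "group")
  }
  out <- one_block(estimates, "all genes")
  if (!is.null(exclude_genes)) {
    out <- dplyr::bind_rows(
      out,
      one_block(dplyr::filter(estimates, !.data$gene %in% exclude_genes),
                paste("excluding", paste(exclude_genes, collapse = ", "))))
  }
  out
}
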