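# Relative S-locus read depth and copy-number classification.
#
# Thrums and homostyles carry the hemizygous S-locus in one or two copies;
# pins lack it entirely. The ratio of mean coding depth over the S-locus to
# mean coding depth genome-wide (Rel_S-locus depth) therefore separates the
# three copy-number classes: ~0.5 haploid, ~1 diploid, ~0 absent.

#' Per-individual mean depth over S-locus and genome-wide coding regions
#'
#' Depth tracks are wide tibbles with columns `chrom`, `pos` (1-based) and
#' one numeric depth column per individual. Positions inside a target
#' interval that have no row in the track count as depth 0, so means are
#' always taken over the full interval width.
#'
#' @param depth Depth track tibble (`chrom`, `pos`, one column per individual).
#' @param slocus_regions S-locus coding intervals (BED-style tibble: `chrom`,
#'   0-based `start`, half-open `end`).
#' @param coding_regions Genome-wide coding intervals (same convention).
#' @return A tibble with columns `individual`, `depth_slocus`,
#'   `depth_genome`, `rel_depth`.
#' @export
summarize_depth <- function(depth, slocus_regions, coding_regions) {
  check_intervals(slocus_regions, "slocus_regions")
  check_intervals(coding_regions, "coding_regions")
  if (!all(c("chrom", "pos") %in% names(depth))) {
    abort("`depth` must have columns chrom, pos plus one column per individual")
  }
  inds <- setdiff(names(depth), c("chrom", "pos"))
  if (length(inds) == 0) abort("`depth` has no individual depth columns")

  mean_over <- function(intervals) {
    width <- interval_width(intervals)
    inside <- positions_in_intervals(depth$chrom, depth$pos, intervals)
    colSums(as.matrix(depth[inside, inds, drop = FALSE])) / width
  }
  ds <- mean_over(slocus_regions)
  dg <- mean_over(coding_regions)
  if (any(dg <= 0)) {
    abort(sprintf(
      "zero genome-wide coding depth for: %s (uninformative individual)",
      paste(inds[dg <= 0], collapse = ", ")))
  }
  tibble(individual = inds, depth_slocus = unname(ds),
         depth_genome = unname(dg), rel_depth = unname(ds / dg))
}

#' Classify S-locus copy number from relative depth
#'
#' A relative depth of approximately 0.5 +/- 0.25 indicates a haploid
#' S-locus and approximately 1 +/- 0.25 a diploid one. The shared boundary
#' 0.75 is assigned to the haploid band (closed upper bound). Values below
#' `threshold_absent` are called `absent` (pins have no reads mapping to the
#' S-locus); anything else is `unclassifiable`.
#'
#' @param summary Output of [summarize_depth()] (or any tibble with
#'   `individual` and `rel_depth` columns).
#' @param threshold_absent Upper bound of the absent band (default 0.05).
#' @return The input with a `copy_number` factor column added
#'   (`absent`, `haploid`, `diploid`, `unclassifiable`).
#' @export
classify_copy_number <- function(summary, threshold_absent = 0.05) {
  if (!all(c("individual", "rel_depth") %in% names(summary))) {
    abort("`summary` must have columns individual and rel_depth")
  }
  if (any(summary$rel_depth < 0)) abort("rel_depth must be non-negative")
  rd <- summary$rel_depth
  call <- dplyr::case_when(
    rd < threshold_absent ~ "absent",
    rd >= 0.25 & rd <= 0.75 ~ "haploid",
    rd > 0.75 & rd <= 1.25 ~ "diploid",
    TRUE ~ "unclassifiable"
  )
  out <- dplyr::mutate(summary, copy_number = factor(
    call, levels = c("absent", "haploid", "diploid", "unclassifiable")))
  class(out) <- c("slocus_depth", class(out))
  out
}

# lookup of consistent (phenotype, copy_number, cypt_status) -> genotype
s_genotype_rules <- function() {
  tibble::tribble(
    ~phenotype,  ~copy_number, ~cypt_status,                        ~genotype,
    "pin",       "absent",     "absent",                            "0/0",
    "thrum",     "haploid",    "functional",                        "S/0",
    "thrum",     "diploid",    "functional",                        "S/S",
    "thrum",     "diploid",    "heterozygous_functional_disrupted", "S/S*",
    "homostyle", "haploid",    "disrupted",                         "S*/0",
    "homostyle", "diploid",    "disrupted",                         "S*/S*"
  )
}

#' Assign the S-locus genotype from copy number, phenotype and CYP^T status
#'
#' Combines the depth-based copy-number call with the floral phenotype and
#' the functional status of CYP^T into one of the six observed S-locus
#' genotypes. Combinations outside the consistency table (for example a
#' homostyle with a functional CYP^T) are flagged `"inconsistent"` rather
#' than coerced.
#'
#' @param calls A tibble with columns `individual`, `copy_number`,
#'   `phenotype` (`pin`/`thrum`/`homostyle`) and `cypt_status`
#'   (`functional`, `disrupted`, `heterozygous_functional_disrupted`,
#'   `absent`).
#' @return The input with a `genotype` column added (`0/0`, `S/0`, `S/S`,
#'   `S/S*`, `S*/0`, `S*/S*`, or `"inconsistent"`).
#' @export
assign_s_genotype <- function(calls) {
  need <- c("individual", "copy_number", "phenotype", "cypt_status")
  if (!all(need %in% names(calls))) {
    abort(sprintf("`calls` must have columns %s", paste(need, collapse = ", ")))
  }
  out <- dplyr::left_join(
    dplyr::mutate(calls, copy_number = as.character(.data$copy_number)),
    s_genotype_rules(),
    by = c("phenotype", "copy_number", "cypt_status"))
  dplyr::mutate(out, genotype = dplyr::coalesce(.data$genotype, "inconsistent"))
}

#' Plot relative S-locus depth by copy-number call
#'
#' @param object Output of [classify_copy_number()].
#' @param ... Unused.
#' @return A ggplot with individuals on the x axis, relative depth on the y
#'   axis, and the classification bands drawn as horizontal ribbons.
#' @export
autoplot.slocus_depth <- function(object, ...) {
  plot_rel_depth(object)
}

#' @rdname autoplot.slocus_depth
#' @param calls Output of [classify_copy_number()].
#' @export
plot_rel_depth <- function(calls) {
  bands <- tibble(
    copy_number = factor(c("haploid", "diploid"),
                         levels = levels(calls$copy_number)),
    lo = c(0.25, 0.75), hi = c(0.75, 1.25))
  ggplot2::ggplot(calls, ggplot2::aes(.data$individual, .data$rel_depth)) +
    ggplot2::geom_rect(
      data = bands, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$lo, ymax = .data$hi,
                   fill = .data$copy_number)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$copy_number)) +
    ggplot2::labs(x = NULL, y = "Relative S-locus depth",
                  colour = "Copy number", fill = "Band") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
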