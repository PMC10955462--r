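# Screens on CYP^T: group-specific SNPs, zero-depth deletions, discordant
# read pairs, and allele classification against the allele catalogue.

#' Screen for SNPs present in homostyles and absent in thrums
#'
#' A site is reported when the alternate allele is observed in at least one
#' individual of the focal group (homostyles) and in none of the contrast
#' group (thrums). The `fixed` flag marks sites where every focal
#' individual with a non-missing call carries the alternate allele.
#'
#' @param genotypes Genotype-matrix tibble: columns `chrom`, `pos`, `ref`,
#'   `alt`, plus one genotype column per individual (`"0/0"`, `"0/1"`,
#'   `"1/1"`, `NA` for missing).
#' @param groups Tibble with columns `individual`, `group`; groups must
#'   include `"homostyle"` and `"thrum"` and every individual belongs to
#'   exactly one group.
#' @param regions Optional interval tibble restricting the screened sites
#'   (introns, promoter, motif intervals).
#' @return A tibble of reported sites with columns `chrom`, `pos`, `ref`,
#'   `alt`, `carriers` (number of focal carriers), `n_called` (focal
#'   individuals with a call) and `fixed`.
#' @export
screen_group_specific_snps <- function(genotypes, groups, regions = NULL) {
  gm <- as_tibble(genotypes)
  hom <- groups$individual[groups$group == "homostyle"]
  thr <- groups$individual[groups$group == "thrum"]
  if (length(hom) == 0 || length(thr) == 0) {
    abort("both the homostyle and the thrum group must be non-empty")
  }
  if (anyDuplicated(groups$individual)) {
    abort("every individual must be assigned to exactly one group")
  }
  missing_cols <- setdiff(c(hom, thr), names(gm))
  if (length(missing_cols) > 0) {
    abort(sprintf("genotype matrix lacks individuals: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(regions)) {
    check_intervals(regions, "regions")
    gm <- gm[positions_in_intervals(gm$chrom, gm$pos, regions), ]
  }
  has_alt <- function(g) !is.na(g) & g %in% c("0/1", "1/0", "1/1", "1")
  hom_mat <- sapply(gm[hom], has_alt)
  thr_mat <- sapply(gm[thr], has_alt)
  called <- function(g) !is.na(g)
  hom_called <- sapply(gm[hom], called)
  if (nrow(gm) == 1) {
    hom_mat <- matrix(hom_mat, nrow = 1); thr_mat <- matrix(thr_mat, nrow = 1)
    hom_called <- matrix(hom_called, nrow = 1)
  }
  carriers <- rowSums(hom_mat)
  n_called <- rowSums(hom_called)
  in_thrums <- rowSums(thr_mat) > 0
  keep <- carriers > 0 & !in_thrums
  kc <- as.integer(carriers[keep])
  kn <- as.integer(n_called[keep])
  dplyr::bind_cols(
    gm[keep, c("chrom", "pos", "ref", "alt")],
    tibble(carriers = kc, n_called = kn, fixed = kc == kn & kn > 0))
}

#' Detect zero-depth runs (candidate deletions) in one individual
#'
#' Maximal runs of consecutive positions with depth 0 inside `region`,
#' retained when at least `min_length` bp long. Positions of the region
#' missing from the track count as depth 0. Runs are annotated with the
#' gene-model features they overlap.
#'
#' @param depth Depth track tibble with columns `chrom`, `pos`, and the
#'   focal individual's depth column.
#' @param individual Name of the depth column to scan.
#' @param region One-row interval tibble (`chrom`, `start`, `end`).
#' @param min_length Minimum run length in bp (default 50; short indels are
#'   the consequence annotator's business, not the depth screen's).
#' @param model Optional [gene_model()] used to annotate overlapped
#'   features (exons, promoter, motifs).
#' @return A tibble with columns `chrom`, `start` (0-based), `end`,
#'   `length`, and `features` (comma-separated overlapped features).
#' @export
detect_zero_depth_runs <- function(depth, individual, region, min_length = 50,
                                   model = NULL) {
  check_intervals(region, "region")
  if (nrow(region) != 1) abort("`region` must be a single interval")
  if (!individual %in% names(depth)) {
    abort(sprintf("no depth column named '%s'", individual))
  }
  pos_all <- seq.int(region$start[1] + 1L, region$end[1])
  d <- rep(0, length(pos_all))
  on_chrom <- depth$chrom == region$chrom[1]
  idx <- match(pos_all, depth$pos[on_chrom])
  hit <- !is.na(idx)
  d[hit] <- depth[[individual]][on_chrom][idx[hit]]

  runs <- rle(d == 0)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  zero <- which(runs$values & runs$lengths >= min_length)
  if (length(zero) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer(), features = character()))
  }
  out <- tibble(
    chrom = region$chrom[1],
    start = pos_all[starts[zero]] - 1L,      # back to 0-based
    end = pos_all[ends[zero]],
    length = runs$lengths[zero])
  out$features <- vapply(seq_len(nrow(out)), function(i) {
    if (is.null(model)) return(NA_character_)
    overlapped_features(model, out$start[i], out$end[i])
  }, character(1))
  out
}

overlapped_features <- function(model, start, end) {
  feats <- character()
  overlaps <- function(iv) iv$start < end & iv$end > start
  ex <- model$exons
  hit_ex <- which(overlaps(ex))
  # exon labels follow transcript order as stored
  if (length(hit_ex) > 0) feats <- c(feats, paste0("exon", hit_ex))
  if (nrow(model$promoter) > 0 && any(overlaps(model$promoter))) {
    feats <- c(feats, "promoter")
  }
  if (nrow(model$motifs) > 0) {
    hit_m <- which(overlaps(model$motifs))
    if (length(hit_m) > 0) {
      feats <- c(feats, paste0("motif:", model$motifs$name[hit_m]))
    }
  }
  if (nrow(model$introns) > 0) {
    hit_i <- which(overlaps(model$introns))
    if (length(hit_i) > 0) feats <- c(feats, paste0("intron", hit_i))
  }
  if (length(feats) == 0) NA_character_ else paste(feats, collapse = ",")
}

#' Tally read-pair orientations over a region
#'
#' Convergent pairs (`+`/`-`, reading towards each other) are normal;
#' same-orientation pairs signal an inversion; mates on different contigs
#' signal a translocation. Pairs with a missing mate are reported as
#' unresolvable.
#'
#' @param pairs Tibble with columns `pair_id`, `contig1`, `pos1`, `strand1`,
#'   `contig2`, `pos2`, `strand2`.
#' @param region One-row interval tibble; a pair is considered when either
#'   mate falls inside it.
#' @return A one-row tibble: `normal_count`, `same_orientation_count`,
#'   `cross_contig_count`, `unresolvable_count`.
#' @export
flag_discordant_pairs <- function(pairs, region) {
  check_intervals(region, "region")
  p <- as_tibble(pairs)
  incomplete <- is.na(p$contig2) | is.na(p$pos2) | is.na(p$strand2) |
    is.na(p$contig1) | is.na(p$pos1) | is.na(p$strand1)
  pc <- p[!incomplete, ]
  in_region <- positions_in_intervals(pc$contig1, pc$pos1, region) |
    positions_in_intervals(pc$contig2, pc$pos2, region)
  pc <- pc[in_region, ]
  cross <- pc$contig1 != pc$contig2
  same <- !cross & pc$strand1 == pc$strand2
  tibble(
    normal_count = sum(!cross & !same),
    same_orientation_count = sum(same),
    cross_contig_count = sum(cross),
    unresolvable_count = sum(incomplete))
}

#' The CYP^T allele catalogue
#'
#' Alleles whose defining mutations are operational here: `CYP^T-1`
#' (functional reference), `CYP^T-2` (premature stop in exon 2), `CYP^T-6`
#' (8-bp frameshift deletion in exon 1), `CYP^T-8` (structural deletion
#' removing exon 1 and the proximal promoter). `CYP^T-3`, `-4`, `-5` and
#' `-7` are placeholders defined in prior work.
#'
#' @return A tibble with columns `allele`, `signature`, `exon`, `status`.
#' @export
cypt_allele_catalogue <- function() {
  tibble::tribble(
    ~allele,   ~signature,            ~exon, ~status,
    "CYP^T-1", "none",                NA_integer_, "functional",
    "CYP^T-2", "stop_gain",           2L,    "disrupted",
    "CYP^T-3", "defined in prior work", NA_integer_, "disrupted",
    "CYP^T-4", "defined in prior work", NA_integer_, "disrupted",
    "CYP^T-5", "defined in prior work", NA_integer_, "disrupted",
    "CYP^T-6", "frameshift",          1L,    "disrupted",
    "CYP^T-7", "defined in prior work", NA_integer_, "disrupted",
    "CYP^T-8", "exon_deletion",       1L,    "disrupted"
  )
}

#' Classify an individual's CYP^T allele
#'
#' Combines coding-consequence calls and zero-depth deletion calls into an
#' allele label from [cypt_allele_catalogue()]. No disruptive event means
#' the functional `CYP^T-1`-like allele; a single disruptive signature maps
#' to its catalogue allele; combinations outside the catalogue are labelled
#' `"novel"` (still `disrupted`), never forced into a known allele.
#'
#' @param consequences Consequence tibble for one individual (output of
#'   [annotate_cds_consequence()] restricted to their variants); may have
#'   zero rows.
#' @param deletions Deletion-call tibble for the same individual (output of
#'   [detect_zero_depth_runs()]); may have zero rows.
#' @param model The CYP^T [gene_model()], used to decide whether a deletion
#'   removes an entire exon.
#' @return A one-row tibble: `allele`, `functional_status`, `evidence`.
#' @export
classify_cypt_allele <- function(consequences, deletions, model) {
  disruptive <- character()
  if (nrow(consequences) > 0) {
    sg <- consequences$class == "stop_gain"
    fs <- consequences$class == "frameshift"
    if (any(sg)) disruptive <- c(disruptive, paste0("stop_gain_exon",
                                                    consequences$exon[sg]))
    if (any(fs)) disruptive <- c(disruptive, paste0("frameshift_exon",
                                                    consequences$exon[fs]))
  }
  if (nrow(deletions) > 0) {
    for (i in seq_len(nrow(deletions))) {
      ex <- model$exons
      covered <- which(ex$start >= deletions$start[i] & ex$end <= deletions$end[i])
      if (length(covered) > 0) {
        disruptive <- c(disruptive, paste0("exon_deletion_exon", covered))
      }
    }
  }
  disruptive <- unique(disruptive)
  if (length(disruptive) == 0) {
    return(tibble(allele = "CYP^T-1", functional_status = "functional",
                  evidence = "no disruptive event"))
  }
  allele <- if (identical(disruptive, "stop_gain_exon2")) "CYP^T-2"
    else if (identical(disruptive, "frameshift_exon1")) "CYP^T-6"
    else if (identical(disruptive, "exon_deletion_exon1")) "CYP^T-8"
    else "novel"
  tibble(allele = allele, functional_status = "disrupted",
         evidence = paste(disruptive, collapse = ";"))
}
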