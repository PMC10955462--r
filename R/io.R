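# Plain-text readers and writers for the pipeline's file formats.
# Coordinates: BED files are 0-based half-open; VCF and depth TSVs are
# 1-based.

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  lines <- unlist(purrr::imap(as.list(sequences), function(s, nm) {
    c(paste0(">", nm),
      substring(s, seq(1, nchar(s), 70), pmin(seq(70, nchar(s) + 69, 70), nchar(s))))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read/write BED interval files
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`).
#' @param path File path.
#' @return `read_bed()` returns an interval tibble.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  utils::write.table(x[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  as_tibble(df)
}

#' Read/write depth TSV tracks
#'
#' Depth tracks are tab-separated with columns `chrom`, `pos` (1-based) and
#' one depth column per individual (samtools-depth style, with a header).
#'
#' @param x Wide depth tibble.
#' @param path File path.
#' @export
write_depth_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE, stringsAsFactors = FALSE))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT-only genotype columns. Invariant sites
#' (alt `NA`) are written with `ALT = .`.
#'
#' @param genotypes Genotype-matrix tibble (`chrom`, `pos`, `ref`, `alt`,
#'   one genotype column per individual).
#' @param path Output path.
#' @export
write_vcf <- function(genotypes, path) {
  inds <- setdiff(names(genotypes), c("chrom", "pos", "ref", "alt"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=slocus",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", inds), collapse = "\t"))
  gt <- as.matrix(genotypes[inds])
  gt[is.na(gt)] <- "./."
  body <- apply(cbind(genotypes$chrom, genotypes$pos, ".",
                      genotypes$ref,
                      ifelse(is.na(genotypes$alt), ".", genotypes$alt),
                      ".", "PASS", ".", "GT", gt), 1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a genotype-matrix tibble
#'
#' Thin wrapper over `vcfR::read.vcfR()` returning the tibble layout the
#' rest of the package consumes. Requires the vcfR package.
#'
#' @param path VCF path.
#' @return A genotype-matrix tibble (`chrom`, `pos`, `ref`, `alt`, one
#'   GT column per individual; `"./."` becomes `NA`).
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[gt %in% c("./.", ".|.", ".")] <- NA_character_
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                ref = fix$REF,
                alt = dplyr::if_else(fix$ALT %in% c(".", ""), NA_character_,
                                     fix$ALT))
  dplyr::bind_cols(out, as_tibble(gt))
}

#' Read variant records with INFO annotations for hard filtering
#'
#' Parses a VCF and extracts the numeric INFO annotations used by
#' [apply_hard_filters()]. Requires the vcfR package.
#'
#' @param path VCF path.
#' @return A tibble with `chrom`, `pos`, `ref`, `alt` and any of `QD`,
#'   `MQ`, `FS`, `MQRankSum`, `ReadPosRankSum`, `DP`, `InbreedingCoeff`
#'   present in the file.
#' @export
read_variants <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                ref = fix$REF, alt = fix$ALT)
  for (key in c("QD", "MQ", "FS", "MQRankSum", "ReadPosRankSum", "DP",
                "InbreedingCoeff")) {
    vals <- suppressWarnings(vcfR::extract.info(v, element = key,
                                                as.numeric = TRUE))
    if (!all(is.na(vals))) out[[key]] <- vals
  }
  out
}
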