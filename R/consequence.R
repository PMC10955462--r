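# Coding-consequence annotation of SNVs and indels against a gene model.

#' Annotate the coding consequence of a variant
#'
#' SNVs inside the CDS are classified by codon translation under the
#' standard genetic code (`synonymous`, `missense`, `stop_gain`); indels
#' whose exonic length is not divisible by 3 are `frameshift`, otherwise
#' `inframe_indel`. Variants not touching an exon are `noncoding`. Indels
#' follow VCF anchoring: `pos` is the 1-based position of the last common
#' base, and the inserted/deleted bases are `substr(ref/alt, 2, ...)`.
#'
#' @param model A [gene_model()].
#' @param ref_cds Reference CDS as a single string (5' to 3'); must
#'   translate without internal stop.
#' @param variants Tibble with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; extra columns are carried through.
#' @return The input with columns `class`, `exon` (5'-to-3' index) and
#'   `protein_change` added.
#' @export
annotate_cds_consequence <- function(model, ref_cds, variants) {
  ref_cds <- toupper(ref_cds)
  if (nchar(ref_cds) != model$cds_length) {
    abort("`ref_cds` length does not match the exonic length of the model")
  }
  if (nchar(ref_cds) %% 3 != 0) abort("CDS length must be divisible by 3")
  aa_ref <- translate_cds(ref_cds)
  if (any(aa_ref[-length(aa_ref)] == "*")) {
    abort("`ref_cds` contains an internal stop codon")
  }

  v <- as_tibble(variants)
  ann <- purrr::pmap_dfr(
    list(v$chrom, v$pos, toupper(v$ref), toupper(v$alt)),
    function(chrom, pos, ref, alt) {
      annotate_one(model, ref_cds, aa_ref, chrom, pos, ref, alt)
    })
  dplyr::bind_cols(v, ann)
}

translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  translate_codon(codons)
}

annotate_one <- function(model, ref_cds, aa_ref, chrom, pos, ref, alt) {
  non <- tibble(class = "noncoding", exon = NA_integer_,
                protein_change = NA_character_)
  if (chrom != model$chrom) return(non)
  len_ref <- nchar(ref); len_alt <- nchar(alt)

  if (len_ref == 1 && len_alt == 1) {  # SNV
    cds_pos <- genomic_to_cds(model, pos)
    if (is.na(cds_pos)) return(non)
    ref_base <- substr(ref_cds, cds_pos, cds_pos)
    strand_base <- if (model$strand == "+") ref else revcomp(ref)
    if (ref_base != strand_base) {
      abort(sprintf("reference mismatch at %s:%d (CDS has %s, variant ref %s)",
                    chrom, pos, ref_base, ref))
    }
    codon_i <- (cds_pos - 1L) %/% 3L + 1L
    within <- (cds_pos - 1L) %% 3L + 1L
    codon <- substr(ref_cds, 3 * codon_i - 2, 3 * codon_i)
    alt_strand <- if (model$strand == "+") alt else revcomp(alt)
    alt_codon <- codon
    substr(alt_codon, within, within) <- alt_strand
    aa0 <- translate_codon(codon); aa1 <- translate_codon(alt_codon)
    cls <- if (aa1 == aa0) "synonymous" else if (aa1 == "*") "stop_gain" else "missense"
    tibble(class = cls, exon = exon_index_of(model, pos),
           protein_change = sprintf("p.%s%d%s", aa0, codon_i,
                                    if (aa1 == "*") "*" else aa1))
  } else {                              # indel (VCF-anchored)
    indel_len <- abs(len_ref - len_alt)
    span <- if (len_ref > len_alt) {
      seq.int(pos + 1L, pos + indel_len)      # deleted bases
    } else {
      pos + 1L                                # insertion point
    }
    cds_hits <- genomic_to_cds(model, span)
    n_exonic <- sum(!is.na(cds_hits))
    if (n_exonic == 0) return(non)
    exonic_len <- if (len_ref > len_alt) n_exonic else indel_len
    exon <- exon_index_of(model, span[!is.na(cds_hits)][1])
    codon_i <- (min(cds_hits, na.rm = TRUE) - 1L) %/% 3L + 1L
    if (exonic_len %% 3 != 0) {
      tibble(class = "frameshift", exon = exon,
             protein_change = sprintf("p.%s%dfs", aa_ref[codon_i], codon_i))
    } else {
      tibble(class = "inframe_indel", exon = exon,
             protein_change = sprintf("p.%s%d_inframe", aa_ref[codon_i], codon_i))
    }
  }
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1)))
}
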