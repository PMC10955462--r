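# Gene models: exon/intron/promoter/motif structure of a gene, with
# genomic <-> CDS coordinate mapping used by the consequence annotator and
# the degeneracy track.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons BED-style tibble (`start` 0-based, `end` half-open) of exon
#'   intervals, ordered 5' to 3' along the transcript (ascending genomic
#'   coordinates on `+`, descending on `-`).
#' @param introns,promoter,motifs Optional interval tibbles; introns are
#'   derived from the exon gaps when omitted. The promoter is the region
#'   expected to contain the transcription-factor binding site (by default
#'   the 3 kb upstream of exon 1); motif intervals are supplied, not
#'   discovered.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand = "+", exons,
                       introns = NULL, promoter = NULL, motifs = NULL) {
  if (!strand %in% c("+", "-")) abort("`strand` must be '+' or '-'")
  exons <- as_tibble(exons)
  if (!all(c("start", "end") %in% names(exons))) {
    abort("`exons` must have columns start, end")
  }
  exons$chrom <- chrom
  genomic_order <- order(exons$start)
  sorted <- exons[genomic_order, ]
  if (any(sorted$start[-1] < sorted$end[-nrow(sorted)])) {
    abort("exons must be non-overlapping")
  }
  # store in transcript (5'->3') order
  exons <- if (strand == "+") sorted else sorted[rev(seq_len(nrow(sorted))), ]
  if (is.null(introns) && nrow(sorted) > 1) {
    introns <- tibble(chrom = chrom,
                      start = sorted$end[-nrow(sorted)],
                      end = sorted$start[-1])
  }
  if (is.null(promoter)) {
    promoter <- if (strand == "+") {
      tibble(chrom = chrom, start = max(0, sorted$start[1] - 3000),
             end = sorted$start[1])
    } else {
      tibble(chrom = chrom, start = sorted$end[nrow(sorted)],
             end = sorted$end[nrow(sorted)] + 3000)
    }
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, introns = as_tibble(introns),
         promoter = as_tibble(promoter),
         motifs = if (is.null(motifs)) tibble(chrom = character(),
                                              name = character(),
                                              start = integer(),
                                              end = integer())
                  else as_tibble(motifs),
         cds_length = sum(exons$end - exons$start)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model %s (%s strand, %s): %d exons, CDS %d bp, %d motif intervals\n",
              x$gene_id, x$strand, x$chrom, nrow(x$exons), x$cds_length,
              nrow(x$motifs)))
  invisible(x)
}

# Map 1-based genomic positions to 1-based CDS positions (NA outside exons).
genomic_to_cds <- function(model, pos) {
  ex <- model$exons
  widths <- ex$end - ex$start
  offsets <- cumsum(c(0, widths[-length(widths)]))
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(ex))) {
    inside <- pos > ex$start[i] & pos <= ex$end[i]
    if (model$strand == "+") {
      out[inside] <- offsets[i] + (pos[inside] - ex$start[i])
    } else {
      out[inside] <- offsets[i] + (ex$end[i] - pos[inside] + 1L)
    }
  }
  as.integer(out)
}

# Map 1-based CDS positions back to genomic positions.
cds_to_genomic <- function(model, cds_pos) {
  ex <- model$exons
  widths <- ex$end - ex$start
  offsets <- cumsum(c(0, widths[-length(widths)]))
  out <- rep(NA_integer_, length(cds_pos))
  for (i in seq_len(nrow(ex))) {
    inside <- cds_pos > offsets[i] & cds_pos <= offsets[i] + widths[i]
    within <- cds_pos[inside] - offsets[i]
    out[inside] <- if (model$strand == "+") ex$start[i] + within
                   else ex$end[i] - within + 1L
  }
  as.integer(out)
}

# Exon index (5'->3') overlapped by a 1-based genomic position, NA if none.
exon_index_of <- function(model, pos) {
  ex <- model$exons
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(ex))) {
    out[pos > ex$start[i] & pos <= ex$end[i]] <- i
  }
  out
}
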