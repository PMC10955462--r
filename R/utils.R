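# shared internal helpers: intervals, codon table, RNG scoping

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Standard nuclear genetic code, codon -> one-letter amino acid ("*" = stop).
codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  # canonical TCAG ordering of the standard code (first base slowest)
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aa, codons)
}

.CODON_TABLE <- codon_table()

translate_codon <- function(codon) {
  unname(.CODON_TABLE[toupper(codon)])
}

# Evaluate `expr` under a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Intervals are BED-convention tibbles: chrom, start (0-based), end (half-open).
check_intervals <- function(x, arg = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns chrom, start, end", arg))
  }
  if (nrow(x) == 0) abort(sprintf("`%s` must contain at least one interval", arg))
  if (any(x$end <= x$start)) abort(sprintf("`%s` has empty or inverted intervals", arg))
  invisible(x)
}

interval_width <- function(x) sum(x$end - x$start)

# Membership of 1-based positions in a BED interval set (same chrom space).
positions_in_intervals <- function(chrom, pos, intervals) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (chrom == intervals$chrom[i] &
                    pos > intervals$start[i] & pos <= intervals$end[i])
  }
  hit
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
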