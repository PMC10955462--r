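# Shared fixtures and independent brute-force oracles used across tests.

# one synthetic genome per test run (deterministic)
test_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- make_gene_model(seed = 7)
    g
  }
})

# --- independent mating-table enumeration for the Crosby recursion --------
# Enumerates every (mother genotype x ovule allele x pollen allele)
# combination explicitly, assembles offspring genotype labels from sorted
# allele pairs, drops untracked classes, applies viability, renormalizes.
oracle_step <- function(state, v, sigma_pin = 0.10, sigma_hom = 1) {
  p <- state[1]; q <- state[2]; r <- state[3]; s <- state[4]
  gametes <- list(
    "0/0"   = c("0" = 1),
    "S/0"   = c("S" = 0.5, "0" = 0.5),
    "S*/0"  = c("S*" = 0.5, "0" = 0.5),
    "S*/S*" = c("S*" = 1))
  pool_tot <- q + r + s
  pool <- if (pool_tot > 0) {
    w <- c(S = 0, `S*` = 0, `0` = 0)
    for (g in c("S/0", "S*/0", "S*/S*")) {
      f <- c("S/0" = q, "S*/0" = r, "S*/S*" = s)[[g]]
      for (a in names(gametes[[g]])) w[a] <- w[a] + f * gametes[[g]][[a]]
    }
    w / sum(w)
  } else NULL
  label <- function(a1, a2) {
    rank <- c("S" = 1, "S*" = 2, "0" = 3)
    paste(c(a1, a2)[order(rank[c(a1, a2)])], collapse = "/")
  }
  out <- c("0/0" = 0, "S/0" = 0, "S*/0" = 0, "S*/S*" = 0)
  add <- function(out, weight, ovules, pollen) {
    for (ov in names(ovules)) for (po in names(pollen)) {
      lab <- label(ov, po)
      if (lab %in% names(out)) {
        out[lab] <- out[lab] + weight * ovules[[ov]] * pollen[[po]]
      }
    }
    out
  }
  # pins
  out <- add(out, p * sigma_pin, c("0" = 1), c("0" = 1))
  if (!is.null(pool)) out <- add(out, p * (1 - sigma_pin), c("0" = 1), pool)
  # thrums: pin pollen only
  if (p > 0) out <- add(out, q, gametes[["S/0"]], c("0" = 1))
  # homostyles
  for (g in c("S*/0", "S*/S*")) {
    f <- c("S*/0" = r, "S*/S*" = s)[[g]]
    out <- add(out, f * sigma_hom, gametes[[g]], gametes[[g]])
    if (!is.null(pool)) out <- add(out, f * (1 - sigma_hom), gametes[[g]], pool)
  }
  out["S*/S*"] <- out["S*/S*"] * v
  out / sum(out)
}

# --- naive pairwise-haplotype nucleotide diversity ------------------------
# Expands every called diploid genotype into two haplotype alleles, then
# averages mismatches over all haplotype pairs with data at each site.
oracle_pi <- function(gm, individuals) {
  hap <- list()
  for (id in individuals) {
    g <- gm[[id]]
    a1 <- rep(NA_integer_, length(g)); a2 <- a1
    a1[g %in% "0/0"] <- 0L; a2[g %in% "0/0"] <- 0L
    a1[g %in% c("0/1", "1/0")] <- 0L; a2[g %in% c("0/1", "1/0")] <- 1L
    a1[g %in% "1/1"] <- 1L; a2[g %in% "1/1"] <- 1L
    hap <- c(hap, list(a1), list(a2))
  }
  diffs <- 0; comps <- 0
  for (i in seq_along(hap)) for (j in seq_len(i - 1)) {
    ok <- !is.na(hap[[i]]) & !is.na(hap[[j]])
    comps <- comps + sum(ok)
    diffs <- diffs + sum(hap[[i]][ok] != hap[[j]][ok])
  }
  if (comps == 0) NA_real_ else diffs / comps
}

# --- consequence classification by whole-CDS translation ------------------
# Classifies an SNV at CDS position `cds_pos` by translating the full
# mutated CDS with Biostrings and comparing protein sequences.
oracle_snv_class <- function(ref_cds, cds_pos, alt_base) {
  mut <- ref_cds
  substr(mut, cds_pos, cds_pos) <- alt_base
  tr <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X"))
  }
  aa_ref <- strsplit(tr(ref_cds), "")[[1]]
  aa_mut <- strsplit(tr(mut), "")[[1]]
  codon_i <- (cds_pos - 1) %/% 3 + 1
  if (aa_mut[codon_i] == aa_ref[codon_i]) "synonymous"
  else if (aa_mut[codon_i] == "*") "stop_gain"
  else "missense"
}

# --- naive zero-run scan --------------------------------------------------
oracle_zero_runs <- function(depths, min_length) {
  runs <- list()
  i <- 1
  n <- length(depths)
  while (i <= n) {
    if (depths[i] == 0) {
      j <- i
      while (j < n && depths[j + 1] == 0) j <- j + 1
      if (j - i + 1 >= min_length) runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

cds_to_genomic_pos <- function(model, cds_pos) {
  slocus:::cds_to_genomic(model, cds_pos)
}

random_state <- function() {
  x <- stats::runif(4)
  x <- x / sum(x)
  crosby_state(x[1], x[2], x[3], x[4])
}
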