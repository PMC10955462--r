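# Synthetic-data generators: gene models and reference sequences, CYP^T
# allele haplotypes, cohorts with known S-locus genotypes, per-site depth
# tracks, read-pair tables and genotype matrices. Every generator is
# deterministic under a fixed seed and emits a machine-readable truth
# record so downstream screens can be validated end to end.

CYPT_ALLELE_LABELS <- c("CYP^T-1", "CYP^T-2", "CYP^T-6", "CYP^T-8")

#' Synthetic S-locus and autosomal gene models with reference sequences
#'
#' Builds the style-length gene CYP^T (5 exons; exon 1 = 286 bp, exon 2 =
#' 227 bp; 3-kb promoter with eight designated motif intervals in the
#' proximal ~1.4 kb), four further S-genes on the same contig, and four
#' paralogs on a separate autosomal contig. Exon 2 carries a serine codon
#' placed so that a single substitution produces a premature stop. Intron
#' and intergenic lengths are free parameters of the emulation with fixed
#' defaults.
#'
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return A list of class `slocus_genome`: `models` (named list of
#'   [gene_model()]), `sequences` (named contig strings), `cds` (named CDS
#'   strings), `slocus_coding`/`genome_coding` (interval tibbles),
#'   `cypt_stop_site` (list: genomic pos, ref, alt of the engineered
#'   exon-2 stop SNV).
#' @export
make_gene_model <- function(seed = 1) {
  with_seed(seed, {
    non_stop <- setdiff(names(.CODON_TABLE), c("TAA", "TAG", "TGA"))
    random_cds <- function(n_codons) {
      body <- sample(non_stop[!non_stop %in% "ATG"], n_codons - 2L,
                     replace = TRUE)
      paste0("ATG", paste(body, collapse = ""), "TAA")
    }
    random_seq <- function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }

    # --- CYP^T: 5 exons of 286/227/330/300/270 bp (CDS 1413, incl. stop)
    exon_len <- c(286L, 227L, 330L, 300L, 270L)
    intron_len <- rep(1000L, 4)
    exon1_start <- 5000L  # 0-based; leaves the full 3-kb promoter upstream
    starts <- exon1_start + cumsum(c(0L, exon_len[-5] + intron_len))
    exons <- tibble(start = starts, end = starts + exon_len)
    motif_offsets <- c(1361L, 917L, 460L, 177L, 174L, 171L, 64L, 15L)
    motifs <- tibble(
      chrom = "Slocus",
      name = paste0("motif", seq_along(motif_offsets)),
      start = exon1_start - motif_offsets - 12L,
      end = exon1_start - motif_offsets)
    cypt <- gene_model("CYP^T", "Slocus", "+", exons, motifs = motifs)

    cds_cypt <- random_cds(471L)  # 1413 / 3
    # engineer a serine codon (TCA) wholly inside exon 2 -> stop by C>G
    stop_codon_i <- 110L
    substr(cds_cypt, 3 * stop_codon_i - 2, 3 * stop_codon_i) <- "TCA"
    cds_stop_pos <- 3L * stop_codon_i - 1L  # middle base of the codon
    stop_site <- list(
      chrom = "Slocus",
      pos = cds_to_genomic(cypt, cds_stop_pos),
      ref = "C", alt = "G")

    # --- four further S-genes downstream on the same contig
    other_s <- c("GLO^T", "CCM^T", "KFB^T", "PUM^T")
    gene_start <- max(cypt$exons$end) + 2000L
    models <- list("CYP^T" = cypt)
    cds <- list("CYP^T" = cds_cypt)
    for (g in other_s) {
      ex <- tibble(start = c(gene_start, gene_start + 900L),
                   end = c(gene_start + 600L, gene_start + 1500L))
      models[[g]] <- gene_model(g, "Slocus", "+", ex)
      cds[[g]] <- random_cds(400L)  # 1200 bp over the two exons
      gene_start <- gene_start + 3000L
    }

    # --- paralogs on the autosomal contig
    paralogs <- c("CYP734A51", "GLO1", "CCM1", "KFB1")
    gene_start <- 2000L
    for (g in paralogs) {
      ex <- tibble(start = c(gene_start, gene_start + 900L),
                   end = c(gene_start + 600L, gene_start + 1500L))
      models[[g]] <- gene_model(g, "Autosome", "+", ex)
      cds[[g]] <- random_cds(400L)
      gene_start <- gene_start + 3000L
    }

    # contig sequences: random backbone with each CDS written into its exons
    write_cds <- function(seq, model, cds_seq) {
      offset <- 0L
      for (i in seq_len(nrow(model$exons))) {
        w <- model$exons$end[i] - model$exons$start[i]
        substr(seq, model$exons$start[i] + 1L, model$exons$end[i]) <-
          substr(cds_seq, offset + 1L, offset + w)
        offset <- offset + w
      }
      seq
    }
    slocus_len <- max(purrr::map_int(models[c("CYP^T", other_s)],
                                     ~ max(.x$exons$end))) + 1000L
    auto_len <- max(purrr::map_int(models[paralogs],
                                   ~ max(.x$exons$end))) + 1000L
    seq_slocus <- random_seq(slocus_len)
    seq_auto <- random_seq(auto_len)
    for (g in c("CYP^T", other_s)) {
      seq_slocus <- write_cds(seq_slocus, models[[g]], cds[[g]])
    }
    for (g in paralogs) {
      seq_auto <- write_cds(seq_auto, models[[g]], cds[[g]])
    }

    coding_of <- function(gs) {
      dplyr::bind_rows(purrr::map(models[gs], ~ .x$exons)) |>
        dplyr::select("chrom", "start", "end") |>
        dplyr::arrange(.data$chrom, .data$start)
    }
    structure(
      list(models = models,
           cds = cds,
           sequences = c(Slocus = seq_slocus, Autosome = seq_auto),
           slocus_coding = coding_of(c("CYP^T", other_s)),
           genome_coding = coding_of(paralogs),
           cypt_stop_site = stop_site),
      class = "slocus_genome")
  })
}

#' @export
print.slocus_genome <- function(x, ...) {
  cat(sprintf(
    "Synthetic S-locus genome: %d gene models on %d contigs (%d bp, %d bp)\n",
    length(x$models), length(x$sequences),
    nchar(x$sequences[1]), nchar(x$sequences[2])))
  invisible(x)
}

#' Built-in CYP^T allele specifications
#'
#' Mutation events defining the operational alleles: `CYP^T-1` none
#' (functional); `CYP^T-2` the engineered exon-2 stop-gain SNV; `CYP^T-6`
#' an 8-bp deletion near the start of exon 1 (frameshift); `CYP^T-8` a
#' 2150-bp structural deletion spanning exon 1 plus the proximal promoter
#' (1600 bp upstream) and the start of intron 1.
#'
#' @param allele One of `"CYP^T-1"`, `"CYP^T-2"`, `"CYP^T-6"`, `"CYP^T-8"`.
#' @param genome A [make_gene_model()] result.
#' @return A list of class `allele_spec`: `allele`, `events` (tibble with
#'   `type`, `pos`, `ref`, `alt`, `start`, `end`, `expected_class`).
#' @export
cypt_allele_spec <- function(allele, genome) {
  model <- genome$models[["CYP^T"]]
  seq <- genome$sequences[["Slocus"]]
  exon1 <- model$exons[1, ]
  events <- switch(allele,
    "CYP^T-1" = tibble(type = character(), pos = integer(),
                       ref = character(), alt = character(),
                       start = integer(), end = integer(),
                       expected_class = character()),
    "CYP^T-2" = {
      st <- genome$cypt_stop_site
      tibble(type = "snv", pos = st$pos, ref = st$ref, alt = st$alt,
             start = NA_integer_, end = NA_integer_,
             expected_class = "stop_gain")
    },
    "CYP^T-6" = {
      # VCF-anchored 8-bp deletion at exon-1 CDS positions 11..18
      anchor <- exon1$start + 10L  # 1-based anchor = CDS position 10
      tibble(type = "indel", pos = anchor,
             ref = substr(seq, anchor, anchor + 8L),
             alt = substr(seq, anchor, anchor),
             start = NA_integer_, end = NA_integer_,
             expected_class = "frameshift")
    },
    "CYP^T-8" = tibble(
      type = "structural_deletion", pos = NA_integer_,
      ref = NA_character_, alt = NA_character_,
      start = exon1$start - 1600L, end = exon1$start + 550L,  # 2150 bp
      expected_class = "exon_deletion"),
    abort(sprintf("unknown CYP^T allele '%s'", allele))
  )
  structure(list(allele = allele, events = events), class = "allele_spec")
}

#' Apply an allele specification to the reference sequence
#'
#' Returns the mutated S-locus haplotype and a truth record of the planted
#' events with their expected consequence classes. Structural deletions
#' excise the span from the haplotype.
#'
#' @param genome A [make_gene_model()] result.
#' @param spec A [cypt_allele_spec()] object.
#' @return A list: `sequence` (mutated haplotype string), `truth` (event
#'   tibble with `allele` added).
#' @export
apply_allele <- function(genome, spec) {
  seq <- genome$sequences[["Slocus"]]
  ev <- spec$events
  n <- nchar(seq)
  for (i in seq_len(nrow(ev))) {
    if (ev$type[i] == "snv") {
      if (ev$pos[i] < 1 || ev$pos[i] > n) abort("SNV position out of bounds")
      if (substr(seq, ev$pos[i], ev$pos[i]) != ev$ref[i]) {
        abort("allele spec reference mismatch")
      }
      substr(seq, ev$pos[i], ev$pos[i]) <- ev$alt[i]
    } else if (ev$type[i] == "indel") {
      del_start <- ev$pos[i] + 1L
      del_len <- nchar(ev$ref[i]) - nchar(ev$alt[i])
      if (del_start + del_len - 1L > n) abort("indel out of bounds")
      seq <- paste0(substr(seq, 1, del_start - 1L),
                    substr(seq, del_start + del_len, n))
      n <- nchar(seq)
    } else if (ev$type[i] == "structural_deletion") {
      if (ev$start[i] < 0 || ev$end[i] > n) abort("deletion span out of bounds")
      seq <- paste0(substr(seq, 1, ev$start[i]),
                    substr(seq, ev$end[i] + 1L, n))
      n <- nchar(seq)
    }
  }
  list(sequence = seq,
       truth = dplyr::mutate(ev, allele = spec$allele, .before = 1))
}

#' Cohort composition presets emulating the sampled populations
#'
#' `"en4t"`, `"en5t"` and `"en6m"` reproduce the three populations with
#' homostyles (collected thrum:pin:homostyle counts 3:4:10, 4:5:10 and
#' 0:0:11; homostyles 40%, 60% and 0% haploid; CYP^T alleles 8 x -6 + 2 x
#' -2, 10 x -2, and 11 x -8 respectively, with the designed `S/S*` thrum in
#' EN4-T and one `S/S` thrum in EN5-T). `"full"` is the nine-population
#' cohort of 37 thrums, 37 pins and 31 homostyles.
#'
#' @param preset One of `"en4t"`, `"en5t"`, `"en6m"`, `"full"`.
#' @return A tibble with one row per population: `population`, `n_thrum`,
#'   `n_pin`, `n_homostyle`, `prop_hap_homostyle`, `hom_allele` (list of
#'   per-homostyle alleles), `n_ss_thrum`, `n_shet_thrum`.
#' @export
cohort_preset <- function(preset = c("full", "en4t", "en5t", "en6m")) {
  preset <- match.arg(preset)
  row <- function(pop, nt, np, nh, p_hap, alleles, n_ss = 0L, n_shet = 0L) {
    tibble(population = pop, n_thrum = nt, n_pin = np, n_homostyle = nh,
           prop_hap_homostyle = p_hap, hom_allele = list(alleles),
           n_ss_thrum = n_ss, n_shet_thrum = n_shet)
  }
  en4 <- row("EN4-T", 3L, 4L, 10L, 0.40,
             c(rep("CYP^T-6", 8), rep("CYP^T-2", 2)), n_shet = 1L)
  en5 <- row("EN5-T", 4L, 5L, 10L, 0.60, rep("CYP^T-2", 10), n_ss = 1L)
  en6 <- row("EN6-M", 0L, 0L, 11L, 0.00, rep("CYP^T-8", 11))
  switch(preset,
    en4t = en4, en5t = en5, en6m = en6,
    full = dplyr::bind_rows(
      row("TR-D", 5L, 5L, 0L, NA_real_, character()),
      row("SK-D", 5L, 5L, 0L, NA_real_, character()),
      row("CH-D", 5L, 5L, 0L, NA_real_, character()),
      row("EN1-D", 5L, 4L, 0L, NA_real_, character()),
      row("EN2-D", 5L, 4L, 0L, NA_real_, character(), n_ss = 1L),
      row("EN3-D", 5L, 5L, 0L, NA_real_, character()),
      en4, en5, en6))
}

#' Simulate a cohort of individuals with known S-locus genotypes
#'
#' Each individual receives a phenotype, an S-locus genotype consistent
#' with it (pin => `0/0`; thrum => `S/0`, `S/S` or `S/S*`; homostyle =>
#' `S*/0` or `S*/S*`), a CYP^T allele and the implied copy number. The
#' composition comes from a preset tibble or is drawn multinomially from a
#' Crosby model state.
#'
#' @param spec A [cohort_preset()]-style tibble.
#' @param state Optional one-row [crosby_state()]; when given with `n`, the
#'   composition of a single population is drawn `multinomial(n, state)`.
#' @param n Population size for the multinomial draw.
#' @param seed Seed for the multinomial draw (unused for fixed presets).
#' @return A tibble: `individual`, `population`, `phenotype`, `genotype`,
#'   `cypt_allele`, `copy_number` (truth table).
#' @export
simulate_cohort <- function(spec = cohort_preset("full"), state = NULL,
                            n = NULL, seed = 1) {
  if (!is.null(state)) {
    if (is.null(n)) abort("`n` is required when drawing from a model state")
    counts <- with_seed(seed,
      stats::rmultinom(1, n, state_vec(state))[, 1])
    geno <- rep(S_GENOTYPES, counts)
    return(tibble(
      individual = sprintf("ind%03d", seq_along(geno)),
      population = "simulated",
      phenotype = dplyr::case_when(
        geno == "0/0" ~ "pin",
        geno == "S/0" ~ "thrum",
        TRUE ~ "homostyle"),
      genotype = geno,
      cypt_allele = dplyr::if_else(geno %in% c("S*/0", "S*/S*"),
                                   "CYP^T-2", "CYP^T-1"),
      copy_number = dplyr::case_when(
        geno == "0/0" ~ "absent",
        geno %in% c("S/0", "S*/0") ~ "haploid",
        TRUE ~ "diploid")))
  }
  purrr::pmap_dfr(spec, function(population, n_thrum, n_pin, n_homostyle,
                                 prop_hap_homostyle, hom_allele,
                                 n_ss_thrum, n_shet_thrum) {
    if (n_homostyle > 0 && length(hom_allele) != n_homostyle) {
      abort(sprintf("population %s: %d homostyles but %d alleles",
                    population, n_homostyle, length(hom_allele)))
    }
    n_hap <- if (n_homostyle > 0) round(n_homostyle * prop_hap_homostyle) else 0L
    hom_geno <- c(rep("S*/0", n_hap), rep("S*/S*", n_homostyle - n_hap))
    if (n_ss_thrum + n_shet_thrum > n_thrum) {
      abort(sprintf("population %s: more diploid thrums than thrums", population))
    }
    thr_geno <- c(rep("S/S", n_ss_thrum), rep("S/S*", n_shet_thrum),
                  rep("S/0", n_thrum - n_ss_thrum - n_shet_thrum))
    out <- tibble(
      population = population,
      phenotype = c(rep("thrum", n_thrum), rep("pin", n_pin),
                    rep("homostyle", n_homostyle)),
      genotype = c(thr_geno, rep("0/0", n_pin), hom_geno),
      cypt_allele = c(
        dplyr::if_else(thr_geno == "S/S*", "CYP^T-1/CYP^T-2", "CYP^T-1"),
        rep(NA_character_, n_pin),
        hom_allele))
    out$copy_number <- dplyr::case_when(
      out$genotype == "0/0" ~ "absent",
      out$genotype %in% c("S/0", "S*/0") ~ "haploid",
      TRUE ~ "diploid")
    out$individual <- sprintf("%s_%02d", gsub("-", "", population),
                              seq_len(nrow(out)))
    dplyr::relocate(out, "individual")
  })
}

#' Simulate per-site depth tracks for a cohort
#'
#' Per-site depth is Poisson (negative binomial when `dispersion > 0`,
#' parameterised by `size = 1/dispersion`) with mean `lambda` on the
#' autosomal contig and on the S-locus contig for diploid carriers, mean
#' `lambda/2` on the S-locus for haploid carriers, and 0 on the S-locus
#' for pins. Carriers of a structural deletion get depth 0 inside the
#' deleted span.
#'
#' @param cohort A [simulate_cohort()] truth table.
#' @param genome A [make_gene_model()] result.
#' @param regions Interval tibble of positions to emit (defaults to all
#'   coding intervals plus the CYP^T promoter and gene body).
#' @param lambda Genome-wide mean depth (default 18.9, the cohort's mean
#'   sequencing depth).
#' @param dispersion Negative-binomial overdispersion (0 = Poisson).
#' @param seed Integer seed.
#' @return A wide depth tibble: `chrom`, `pos`, one column per individual.
#' @export
simulate_depth <- function(cohort, genome, regions = NULL, lambda = 18.9,
                           dispersion = 0, seed = 1) {
  if (is.null(regions)) {
    cypt <- genome$models[["CYP^T"]]
    span <- tibble(chrom = "Slocus",
                   start = min(cypt$promoter$start),
                   end = max(cypt$exons$end) + 200L)
    regions <- dplyr::bind_rows(span, genome$slocus_coding,
                                genome$genome_coding)
  }
  check_intervals(regions)
  pos_tbl <- regions |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(pos = unique(sort(unlist(
      purrr::map2(.data$start, .data$end, ~ seq.int(.x + 1L, .y))))))
  draw <- function(n, mu) {
    if (mu <= 0) return(rep(0L, n))
    if (dispersion > 0) stats::rnbinom(n, size = 1 / dispersion, mu = mu)
    else stats::rpois(n, mu)
  }
  del_span <- cypt_deletion_span(genome)
  with_seed(seed, {
    cols <- purrr::map(seq_len(nrow(cohort)), function(i) {
      ind <- cohort[i, ]
      mu_s <- switch(ind$copy_number,
                     absent = 0, haploid = lambda / 2, diploid = lambda)
      d <- ifelse(pos_tbl$chrom == "Slocus",
                  NA_integer_, draw(nrow(pos_tbl), lambda))
      on_s <- pos_tbl$chrom == "Slocus"
      d[on_s] <- draw(sum(on_s), mu_s)
      if (!is.na(ind$cypt_allele) && ind$cypt_allele == "CYP^T-8") {
        in_del <- on_s & pos_tbl$pos > del_span$start & pos_tbl$pos <= del_span$end
        d[in_del] <- 0L
      }
      d
    })
    names(cols) <- cohort$individual
    dplyr::bind_cols(pos_tbl, as_tibble(cols))
  })
}

cypt_deletion_span <- function(genome) {
  ev <- cypt_allele_spec("CYP^T-8", genome)$events
  list(start = ev$start[1], end = ev$end[1])
}

#' Depth summaries for many simulated individuals without full tracks
#'
#' Draws per-site Poisson (or negative binomial) depths over `l_slocus`
#' S-locus coding sites and `l_genome` genome-wide coding sites per
#' individual, and returns the per-individual means and relative depth.
#' Used for calibration runs with hundreds of individuals, where
#' materialising wide depth tracks is pointless.
#'
#' @param copy_number Character vector (one entry per simulated individual)
#'   of `"absent"`, `"haploid"`, `"diploid"`.
#' @param lambda Genome-wide mean depth.
#' @param l_slocus,l_genome Number of simulated sites per region (default
#'   50 kb each).
#' @param dispersion Negative-binomial overdispersion (0 = Poisson).
#' @param seed Integer seed.
#' @return A tibble: `individual`, `truth`, `depth_slocus`, `depth_genome`,
#'   `rel_depth`.
#' @export
simulate_depth_summaries <- function(copy_number, lambda = 19,
                                     l_slocus = 50000, l_genome = 50000,
                                     dispersion = 0, seed = 1) {
  draw_mean <- function(n, mu) {
    if (mu <= 0) return(0)
    if (dispersion > 0) mean(stats::rnbinom(n, size = 1 / dispersion, mu = mu))
    else mean(stats::rpois(n, mu))
  }
  with_seed(seed, {
    mu_s <- c(absent = 0, haploid = lambda / 2, diploid = lambda)[copy_number]
    ds <- vapply(mu_s, function(m) draw_mean(l_slocus, m), numeric(1))
    dg <- vapply(seq_along(copy_number),
                 function(i) draw_mean(l_genome, lambda), numeric(1))
    tibble(individual = sprintf("sim%04d", seq_along(copy_number)),
           truth = copy_number,
           depth_slocus = unname(ds), depth_genome = dg,
           rel_depth = unname(ds) / dg)
  })
}

#' Simulate a genotype matrix with group-specific diversity
#'
#' Sites are independent. Within each group a site is polymorphic with
#' probability `2 * theta` and then has allele frequency 0.5, giving
#' per-site expected heterozygosity `theta`. Outcrossing groups draw
#' genotypes in Hardy-Weinberg proportions; groups listed in
#' `selfing_groups` draw with inbreeding coefficient `f_selfing` (excess
#' homozygosity). Calls go missing independently at `missing_rate`.
#' Invariant sites are emitted (alt `NA`), so the matrix carries its own
#' callability information.
#'
#' @param groups Tibble `individual`, `group`.
#' @param theta Named numeric: per-site expected heterozygosity per group.
#' @param n_sites Number of callable sites (default 10000).
#' @param missing_rate Probability a call is missing (default 0).
#' @param selfing_groups Groups generated with excess homozygosity.
#' @param f_selfing Inbreeding coefficient for selfing groups (default 0.9).
#' @param chrom,offset Coordinates of the emitted sites.
#' @param seed Integer seed.
#' @return A genotype-matrix tibble (`chrom`, `pos`, `ref`, `alt`, one
#'   column per individual).
#' @export
simulate_genotype_matrix <- function(groups, theta, n_sites = 10000,
                                     missing_rate = 0,
                                     selfing_groups = character(),
                                     f_selfing = 0.9,
                                     chrom = "sim", offset = 0L, seed = 1) {
  if (any(theta < 0) || any(2 * theta > 1)) {
    abort("`theta` values must lie in [0, 0.5]")
  }
  miss <- missing_rate
  with_seed(seed, {
    out <- tibble(chrom = chrom, pos = offset + seq_len(n_sites),
                  ref = "A", alt = NA_character_)
    for (grp in unique(groups$group)) {
      th <- theta[[grp]]
      if (is.null(th)) abort(sprintf("no theta for group '%s'", grp))
      inds <- groups$individual[groups$group == grp]
      poly <- stats::runif(n_sites) < 2 * th
      f_in <- if (grp %in% selfing_groups) f_selfing else 0
      # genotype probabilities at freq 0.5 with inbreeding F
      p_hom <- 0.25 + 0.25 * f_in
      probs <- c(p_hom, 0.5 * (1 - f_in), p_hom)  # 0/0, 0/1, 1/1
      for (id in inds) {
        g <- rep("0/0", n_sites)
        n_poly <- sum(poly)
        if (n_poly > 0) {
          g[poly] <- sample(c("0/0", "0/1", "1/1"), n_poly,
                            replace = TRUE, prob = probs)
        }
        if (miss > 0) g[stats::runif(n_sites) < miss] <- NA_character_
        out[[id]] <- g
      }
      if (any(poly)) out$alt[poly] <- "T"
    }
    out
  })
}

#' Simulate a read-pair table with planted discordant pairs
#'
#' @param n_normal,n_same_orientation,n_cross_contig Numbers of convergent,
#'   same-orientation (inversion-signal) and cross-contig
#'   (translocation-signal) pairs to plant inside `region`.
#' @param region One-row interval tibble where mate 1 is placed.
#' @param other_contig Contig name for translocated mates.
#' @param seed Integer seed.
#' @return A tibble: `pair_id`, `contig1`, `pos1`, `strand1`, `contig2`,
#'   `pos2`, `strand2`.
#' @export
simulate_read_pairs <- function(n_normal, n_same_orientation = 0,
                                n_cross_contig = 0, region,
                                other_contig = "Autosome", seed = 1) {
  check_intervals(region, "region")
  with_seed(seed, {
    n <- n_normal + n_same_orientation + n_cross_contig
    pos1 <- sample(seq.int(region$start[1] + 1L, region$end[1] - 400L),
                   n, replace = TRUE)
    kind <- rep(c("normal", "same", "cross"),
                c(n_normal, n_same_orientation, n_cross_contig))
    tibble(
      pair_id = sprintf("pair%04d", seq_len(n)),
      contig1 = region$chrom[1],
      pos1 = pos1,
      strand1 = "+",
      contig2 = dplyr::if_else(kind == "cross", other_contig, region$chrom[1]),
      pos2 = dplyr::if_else(kind == "cross",
                            sample(1000:5000, n, replace = TRUE),
                            pos1 + 300L),
      strand2 = dplyr::if_else(kind == "same", "+", "-"))
  })
}
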