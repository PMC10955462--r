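# Observed genotype-frequency tables and chi-squared goodness of fit
# against Crosby-model expectations over the (viability x generation) grid.

#' Observed S-locus genotype table from phenotype counts
#'
#' Splits surveyed phenotype counts into the four S-locus genotype classes:
#' pins are all `0/0`; homostyles are split between `S*/0` and `S*/S*` by
#' the classified proportions (from the depth-based genotyping of a
#' subsample); thrums may analogously be split over `S/0`, `S/S` and
#' `S/S*`. Fractional counts are rounded to the nearest integer and any
#' residual is assigned to the larger class, so the counts always sum to
#' the surveyed totals.
#'
#' @param population Population label.
#' @param n_thrum,n_pin,n_homostyle Surveyed phenotype counts.
#' @param hom_props Length-2 numeric `c(S*/0, S*/S*)` proportions among
#'   homostyles (must sum to 1).
#' @param thrum_props Length-3 numeric `c(S/0, S/S, S/S*)` proportions
#'   among thrums (default all `S/0`).
#' @return A tibble of class `genotype_table`: `population`, `genotype`,
#'   `count`, `freq` (frequency over all collected individuals).
#' @export
#' @examples
#' observed_genotype_table("EN4-T", 3, 4, 10, hom_props = c(0.40, 0.60))
observed_genotype_table <- function(population, n_thrum, n_pin, n_homostyle,
                                    hom_props = c(0, 1),
                                    thrum_props = c(1, 0, 0)) {
  counts <- c(n_thrum, n_pin, n_homostyle)
  if (any(counts < 0)) abort("phenotype counts must be non-negative")
  total <- sum(counts)
  if (total == 0) abort("zero collected individuals")
  split_count <- function(n, props, labels) {
    if (abs(sum(props) - 1) > 1e-6 || any(props < 0)) {
      abort("split proportions must be non-negative and sum to 1")
    }
    k <- round(n * props)
    resid <- n - sum(k)
    if (resid != 0) k[which.max(k)] <- k[which.max(k)] + resid
    stats::setNames(k, labels)
  }
  hom <- split_count(n_homostyle, hom_props, c("S*/0", "S*/S*"))
  thr <- split_count(n_thrum, thrum_props, c("S/0", "S/S", "S/S*"))
  out <- tibble(
    population = population,
    genotype = c("0/0", names(thr), names(hom)),
    count = as.integer(c(n_pin, thr, hom)))
  out$freq <- out$count / total
  class(out) <- c("genotype_table", class(out))
  out
}

# collapse a genotype table to the four model classes (S/0, S/S and S/S*
# all carry a functional haplotype and are pooled into the thrum class)
model_counts <- function(observed) {
  cls <- dplyr::case_when(
    observed$genotype == "0/0" ~ "0/0",
    observed$genotype %in% c("S/0", "S/S", "S/S*") ~ "S/0",
    TRUE ~ observed$genotype)
  vapply(S_GENOTYPES, function(g) sum(observed$count[cls == g]), numeric(1))
}

#' Chi-squared goodness of fit of an observed table to expected frequencies
#'
#' Expected counts are the expected frequencies scaled to the observed
#' total. Cells with expected count 0 and observed count 0 are dropped
#' (reducing the degrees of freedom); an observed count in a cell of
#' expected frequency 0 makes the table incompatible (`chi2 = Inf`,
#' `p = 0`). `df` is the number of included cells minus 1.
#'
#' @param observed A [observed_genotype_table()] result (or any tibble with
#'   `genotype` and `count`).
#' @param expected A one-row state tibble of expected frequencies
#'   (columns `p`, `q`, `r`, `s`), e.g. a row of [crosby_grid()].
#' @return A one-row tibble: `chi2`, `df`, `p_raw`.
#' @export
chisq_fit <- function(observed, expected) {
  obs <- model_counts(observed)
  n <- sum(obs)
  if (n <= 0) abort("observed table has zero total count")
  ef <- unlist(expected[1, c("p", "q", "r", "s")], use.names = FALSE)
  if (abs(sum(ef) - 1) > 1e-6) abort("expected frequencies must sum to 1")
  drop <- ef == 0 & obs == 0
  if (sum(!drop) < 2) abort("fewer than 2 cells with data to compare")
  if (any(ef == 0 & obs > 0)) {
    return(tibble(chi2 = Inf, df = sum(!drop) - 1L, p_raw = 0))
  }
  e <- ef[!drop] * n
  o <- obs[!drop]
  chi2 <- sum((o - e)^2 / e)
  df <- length(o) - 1L
  tibble(chi2 = chi2, df = df,
         p_raw = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Fit observed tables against an expectation grid
#'
#' One chi-squared test per (population, viability, generation) cell, with
#' Bonferroni adjustment. The default family is all grid cells tested
#' within a population (`family = "per_population"`); `"global"` uses every
#' cell across populations, and a fixed integer can be supplied.
#'
#' @param observed_tables A list of [observed_genotype_table()] results (or
#'   one table).
#' @param expected_grid Output of [crosby_grid()] (`v`, `generation`, `p`,
#'   `q`, `r`, `s`).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param family `"per_population"`, `"global"`, or an integer family size.
#' @return A tibble of class `slocus_fit` with one row per cell:
#'   `population`, `v`, `generation`, `chi2`, `df`, `p_raw`, `p_adjusted`,
#'   `significant`, `compatible`.
#' @export
fit_grid <- function(observed_tables, expected_grid, alpha = 0.05,
                     family = "per_population") {
  if (inherits(observed_tables, "genotype_table")) {
    observed_tables <- list(observed_tables)
  }
  res <- purrr::map_dfr(observed_tables, function(obs) {
    purrr::map_dfr(seq_len(nrow(expected_grid)), function(i) {
      row <- expected_grid[i, ]
      dplyr::bind_cols(
        tibble(population = obs$population[1], v = row$v,
               generation = row$generation),
        chisq_fit(obs, row))
    })
  })
  m <- if (identical(family, "per_population")) {
    nrow(expected_grid)
  } else if (identical(family, "global")) {
    nrow(res)
  } else if (is_scalar_number(family)) {
    as.integer(family)
  } else {
    abort("`family` must be 'per_population', 'global', or an integer")
  }
  res <- res |>
    dplyr::mutate(
      p_adjusted = pmin(1, .data$p_raw * m),
      significant = .data$p_adjusted < alpha,
      compatible = !.data$significant)
  attr(res, "alpha") <- alpha
  attr(res, "family_size") <- m
  class(res) <- c("slocus_fit", class(res))
  res
}

#' @rdname fit_grid
#' @param x A `slocus_fit` object.
#' @param ... Unused.
#' @export
tidy.slocus_fit <- function(x, ...) {
  as_tibble(x)
}

#' @rdname fit_grid
#' @export
glance.slocus_fit <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_compatible = sum(x$compatible),
    alpha = attr(x, "alpha"),
    family_size = attr(x, "family_size"))
}

#' Plot the compatibility matrix of a fit grid
#'
#' @param object A [fit_grid()] result.
#' @param ... Unused.
#' @return A ggplot tile map of (generation x viability) per population,
#'   shaded by compatibility with the model expectations.
#' @export
autoplot.slocus_fit <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(factor(.data$generation), factor(.data$v),
                               fill = .data$compatible)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = "Generation", y = "Viability v",
                  fill = "Compatible") +
    ggplot2::theme_minimal()
}
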