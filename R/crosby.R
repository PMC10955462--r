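# Deterministic genotype-frequency recursion for the hemizygous Primula
# S-locus (Crosby's model), with viability selection on S*/S* homostyles.
#
# State space: frequencies of the four tracked genotypes
#   p = pin   (0/0)    locus absent
#   q = thrum (S/0)    hemizygous functional haplotype
#   r = homostyle (S*/0)   hemizygous disrupted haplotype
#   s = homostyle (S*/S*)  homozygous disrupted haplotype

S_GENOTYPES <- c("0/0", "S/0", "S*/0", "S*/S*")

#' Model parameters for the Crosby recursion
#'
#' @param v Viability of `S*/S*` offspring relative to the other three
#'   genotypes, in `(0, 1]`. The study's two focal settings are `v = 1`
#'   (equal viability) and `v = 0.65` (35% lower viability); the comparison
#'   grid adds 0.9, 0.8, 0.7, 0.6 and 0.5.
#' @param sigma_pin Selfing rate of pins (default 0.10, the model's classical
#'   assumption; setting it to 0 does not change the qualitative outcome).
#' @param sigma_hom Selfing rate of homostyles (default 1: homostyles are
#'   self-compatible with anthers and stigma at the same level, and the
#'   four-genotype state space excludes the `S/S*` products of outcrossed
#'   homostyle ovules).
#' @param tol Convergence tolerance on the L-infinity change between
#'   consecutive states (default 1e-10).
#' @param max_gens Iteration cap for equilibrium search (default 1e5).
#' @return A list of class `crosby_params`.
#' @export
#' @examples
#' crosby_params(v = 0.65)
crosby_params <- function(v = 1, sigma_pin = 0.10, sigma_hom = 1,
                          tol = 1e-10, max_gens = 100000L) {
  if (!is_scalar_number(v) || v <= 0 || v > 1) {
    abort("`v` must be a single number in (0, 1]")
  }
  for (nm in c("sigma_pin", "sigma_hom")) {
    val <- get(nm)
    if (!is_scalar_number(val) || val < 0 || val > 1) {
      abort(sprintf("`%s` must be a single number in [0, 1]", nm))
    }
  }
  structure(
    list(v = v, sigma_pin = sigma_pin, sigma_hom = sigma_hom,
         tol = tol, max_gens = as.integer(max_gens)),
    class = "crosby_params"
  )
}

#' @export
print.crosby_params <- function(x, ...) {
  cat(sprintf(
    "Crosby model parameters: v = %g, sigma_pin = %g, sigma_hom = %g (tol %g, max %d gens)\n",
    x$v, x$sigma_pin, x$sigma_hom, x$tol, x$max_gens))
  invisible(x)
}

#' Population state of the four S-locus genotypes
#'
#' @param p,q,r,s Frequencies of `0/0` (pin), `S/0` (thrum), `S*/0`
#'   (hemizygous homostyle) and `S*/S*` (homozygous homostyle).
#' @param generation Non-negative generation index (default 0).
#' @return A one-row tibble with columns `generation`, `p`, `q`, `r`, `s`.
#' @export
#' @examples
#' crosby_state(0.45, 0.45, 0.05, 0.05)
crosby_state <- function(p, q, r, s, generation = 0L) {
  x <- c(p, q, r, s)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort("all four genotype frequencies must lie in [0, 1]")
  }
  if (abs(sum(x) - 1) > 1e-9) {
    abort(sprintf("genotype frequencies must sum to 1 (got %.12f)", sum(x)))
  }
  tibble(generation = as.integer(generation), p = p, q = q, r = r, s = s)
}

state_vec <- function(state) {
  unlist(state[1, c("p", "q", "r", "s")], use.names = FALSE)
}

#' Gamete distribution of an S-locus genotype
#'
#' Mendelian segregation at a hemizygous locus: the missing homolog is
#' transmitted as the null haplotype `0`.
#'
#' @param genotype One of `"0/0"`, `"S/0"`, `"S*/0"`, `"S*/S*"`.
#' @return A tibble with columns `allele` (`"S"`, `"S*"`, `"0"`) and `prob`.
#' @export
#' @examples
#' gamete_distribution("S*/0")
gamete_distribution <- function(genotype) {
  probs <- switch(genotype,
    "0/0"   = c("0" = 1),
    "S/0"   = c("S" = 0.5, "0" = 0.5),
    "S*/0"  = c("S*" = 0.5, "0" = 0.5),
    "S*/S*" = c("S*" = 1),
    abort(sprintf("unknown S-locus genotype: '%s'", genotype))
  )
  tibble(allele = names(probs), prob = unname(probs))
}

# Allele frequencies in the high-anther pollen pool (thrums + homostyles,
# export proportional to genotype frequency). Returns c(S, S*, `0`) probs,
# or NULL when the pool is empty.
high_anther_pool <- function(q, r, s) {
  tot <- q + r + s
  if (tot <= 0) return(NULL)
  c(S = (q / 2) / tot, `S*` = (r / 2 + s) / tot, `0` = (q / 2 + r / 2) / tot)
}

#' Advance the Crosby recursion by one generation
#'
#' Offspring of every maternal genotype are accumulated over the mating
#' table: pins self at rate `sigma_pin` and otherwise receive high-anther
#' pollen (thrums and homostyles, export proportional to frequency); thrums
#' are self-incompatible and receive pin pollen only (so leave no offspring
#' when pins are absent); homostyles self at rate `sigma_hom` and otherwise
#' receive high-anther pollen. `S*/S*` offspring are weighted by the
#' viability `v` before the offspring vector is renormalized. Offspring
#' falling outside the four tracked genotypes (`S/S*`, possible only when
#' `sigma_hom < 1`) are dropped; the dropped mass is recorded in the
#' `"untracked_mass"` attribute.
#'
#' @param state A one-row state tibble from [crosby_state()].
#' @param params A [crosby_params()] object.
#' @return The next-generation state (one-row tibble, generation incremented).
#' @export
#' @examples
#' crosby_step(crosby_state(0, 0, 1, 0), crosby_params(v = 1))
crosby_step <- function(state, params = crosby_params()) {
  x <- state_vec(state)
  if (any(x < 0) || abs(sum(x) - 1) > 1e-9) {
    abort("`state` is not a normalized frequency vector")
  }
  p <- x[1]; q <- x[2]; r <- x[3]; s <- x[4]
  w <- c("0/0" = 0, "S/0" = 0, "S*/0" = 0, "S*/S*" = 0)
  untracked <- 0
  pool <- high_anther_pool(q, r, s)

  # pin mothers: ovule allele always 0
  w["0/0"] <- w["0/0"] + p * params$sigma_pin
  if (!is.null(pool)) {
    oc <- p * (1 - params$sigma_pin)
    w["S/0"]  <- w["S/0"]  + oc * pool["S"]
    w["S*/0"] <- w["S*/0"] + oc * pool["S*"]
    w["0/0"]  <- w["0/0"]  + oc * pool["0"]
  }

  # thrum mothers: self-incompatible, pin pollen (allele 0) only
  if (p > 0 && q > 0) {
    w["S/0"] <- w["S/0"] + q / 2
    w["0/0"] <- w["0/0"] + q / 2
  }

  # S*/0 homostyle mothers
  sh <- params$sigma_hom
  w["0/0"]   <- w["0/0"]   + r * sh / 4
  w["S*/0"]  <- w["S*/0"]  + r * sh / 2
  w["S*/S*"] <- w["S*/S*"] + r * sh / 4
  if (!is.null(pool) && sh < 1) {
    oc <- r * (1 - sh)  # ovule 1/2 S*, 1/2 0
    w["S*/S*"] <- w["S*/S*"] + oc * 0.5 * pool["S*"]
    w["S*/0"]  <- w["S*/0"]  + oc * (0.5 * pool["0"] + 0.5 * pool["S*"])
    w["0/0"]   <- w["0/0"]   + oc * 0.5 * pool["0"]
    w["S/0"]   <- w["S/0"]   + oc * 0.5 * pool["S"]
    untracked  <- untracked  + oc * 0.5 * pool["S"]  # S pollen x S* ovule
  }

  # S*/S* homostyle mothers: all ovules S*
  w["S*/S*"] <- w["S*/S*"] + s * sh
  if (!is.null(pool) && sh < 1) {
    oc <- s * (1 - sh)
    w["S*/S*"] <- w["S*/S*"] + oc * pool["S*"]
    w["S*/0"]  <- w["S*/0"]  + oc * pool["0"]
    untracked  <- untracked  + oc * pool["S"]
  }

  w["S*/S*"] <- w["S*/S*"] * params$v
  tot <- sum(w)
  if (tot <= 0) {
    abort("degenerate population: no compatible matings produce offspring")
  }
  w <- w / tot
  out <- crosby_state(w[["0/0"]], w[["S/0"]], w[["S*/0"]], w[["S*/S*"]],
                      generation = state$generation[1] + 1L)
  attr(out, "untracked_mass") <- unname(untracked)
  out
}

#' Iterate the recursion and collect the trajectory
#'
#' @inheritParams crosby_step
#' @param n_gens Number of generations to iterate (>= 0).
#' @return A tibble of class `crosby_trajectory` with one row per generation
#'   from 0 to `n_gens` (columns `generation`, `p`, `q`, `r`, `s`) and the
#'   parameters in the `"params"` attribute.
#' @export
#' @examples
#' crosby_trajectory(crosby_state(0.495, 0.495, 0.01, 0), crosby_params(v = 0.65), 40)
crosby_trajectory <- function(state, params = crosby_params(), n_gens) {
  if (!is_scalar_number(n_gens) || n_gens < 0) abort("`n_gens` must be >= 0")
  n_gens <- as.integer(n_gens)
  rows <- vector("list", n_gens + 1L)
  cur <- state
  rows[[1]] <- cur
  if (n_gens > 0) {
    for (g in seq_len(n_gens)) {
      cur <- crosby_step(cur, params)
      rows[[g + 1L]] <- cur
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- params
  class(out) <- c("crosby_trajectory", class(out))
  out
}

#' Iterate the recursion to equilibrium
#'
#' Runs [crosby_step()] until the L-infinity change between consecutive
#' states drops below `params$tol`, or `params$max_gens` is reached.
#'
#' @inheritParams crosby_step
#' @return A list of class `crosby_equilibrium` with elements `state` (final
#'   one-row state tibble), `converged` (logical) and `params`.
#' @export
#' @examples
#' eq <- crosby_equilibrium(crosby_state(0.45, 0.45, 0.05, 0.05), crosby_params(v = 1))
#' eq$state
crosby_equilibrium <- function(state, params = crosby_params()) {
  cur <- state
  converged <- FALSE
  for (i in seq_len(params$max_gens)) {
    nxt <- crosby_step(cur, params)
    if (max(abs(state_vec(nxt) - state_vec(cur))) < params$tol) {
      cur <- nxt
      converged <- TRUE
      break
    }
    cur <- nxt
  }
  structure(list(state = cur, converged = converged, params = params),
            class = "crosby_equilibrium")
}

#' @export
print.crosby_equilibrium <- function(x, ...) {
  v <- state_vec(x$state)
  cat(sprintf(
    "Crosby equilibrium (v = %g, %s after %d generations)\n  0/0 = %.6f  S/0 = %.6f  S*/0 = %.6f  S*/S* = %.6f\n",
    x$params$v, if (x$converged) "converged" else "NOT converged",
    x$state$generation[1], v[1], v[2], v[3], v[4]))
  invisible(x)
}

#' @rdname crosby_equilibrium
#' @param x A `crosby_equilibrium` object.
#' @param ... Unused.
#' @export
glance.crosby_equilibrium <- function(x, ...) {
  dplyr::mutate(x$state, v = x$params$v, converged = x$converged,
                .before = "generation")
}

#' Expected genotype frequencies over a (viability x generation) grid
#'
#' One deterministic trajectory per viability value, sampled at the
#' requested generations. The default grid is the one used to compare
#' natural populations against the model: v in {1, 0.9, 0.8, 0.7, 0.65,
#' 0.6, 0.5} at generations 10, 20, 30 and 40 after the onset of homostyly.
#'
#' @inheritParams crosby_step
#' @param v_values Viability values, each in (0, 1].
#' @param generations Sorted non-negative generation indices to report.
#' @param base Base [crosby_params()] supplying the selfing rates.
#' @return A tibble with columns `v`, `generation`, `p`, `q`, `r`, `s`.
#' @export
#' @examples
#' crosby_grid(crosby_state(0.495, 0.495, 0.01, 0))
crosby_grid <- function(state,
                        v_values = c(1, 0.9, 0.8, 0.7, 0.65, 0.6, 0.5),
                        generations = c(10L, 20L, 30L, 40L),
                        base = crosby_params()) {
  if (length(v_values) == 0 || any(v_values <= 0 | v_values > 1)) {
    abort("`v_values` must be non-empty with every value in (0, 1]")
  }
  if (is.unsorted(generations)) abort("`generations` must be sorted ascending")
  purrr::map_dfr(v_values, function(v) {
    pars <- crosby_params(v = v, sigma_pin = base$sigma_pin,
                          sigma_hom = base$sigma_hom,
                          tol = base$tol, max_gens = base$max_gens)
    traj <- crosby_trajectory(state, pars, max(generations))
    dplyr::filter(as_tibble(traj), .data$generation %in% generations) |>
      dplyr::mutate(v = v, .before = "generation")
  })
}

#' Plot a genotype-frequency trajectory
#'
#' @param object A [crosby_trajectory()] result.
#' @param ... Unused.
#' @return A ggplot of the four genotype frequencies against generation.
#' @export
autoplot.crosby_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("p", "q", "r", "s"),
                              names_to = "class", values_to = "frequency")
  long$genotype <- factor(
    S_GENOTYPES[match(long$class, c("p", "q", "r", "s"))], levels = S_GENOTYPES)
  pars <- attr(object, "params")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$frequency,
                                     colour = .data$genotype)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      title = sprintf("S-locus genotype frequencies (v = %g)", pars$v),
      x = "Generation", y = "Frequency", colour = "Genotype") +
    ggplot2::theme_minimal()
}
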