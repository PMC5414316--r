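#' Configuration for the random-mating population simulator
#'
#' Defaults follow the simulated efficiency study design: 1,000 offspring
#' sampled from random mating of 100 parents over 10 non-overlapping
#' generations, with 100 unlinked biallelic markers. Founder allele
#' frequencies are drawn uniformly from `founder_maf` (default 0.1--0.5,
#' chosen to keep markers comfortably polymorphic; the original study does
#' not state founder frequencies).
#'
#' @param n_founders number of founder individuals (>= 2).
#' @param n_generations number of discrete generations of random mating
#'   (>= 1).
#' @param n_offspring number of individuals in the final, returned
#'   generation.
#' @param n_markers number of unlinked biallelic markers.
#' @param founder_maf length-2 vector of lower/upper founder allele
#'   frequency bounds, each in (0, 1).
#' @param h2 target narrow-sense heritability in (0, 1) for
#'   [simulate_phenotypes()].
#' @param seed optional integer RNG seed for full reproducibility.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 100, n_generations = 10,
                       n_offspring = 1000, n_markers = 100,
                       founder_maf = c(0.1, 0.5), h2 = 0.5, seed = NULL) {
  stopifnot(n_founders >= 2, n_generations >= 1, n_offspring >= 1,
            n_markers >= 1)
  if (length(founder_maf) != 2L || founder_maf[1L] <= 0 ||
      founder_maf[2L] >= 1 || founder_maf[1L] > founder_maf[2L])
    stop("founder_maf must be bounds (low, high) with 0 < low <= high < 1")
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_offspring = as.integer(n_offspring),
                 n_markers = as.integer(n_markers),
                 founder_maf = as.numeric(founder_maf), h2 = h2,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotypes by random mating of a founder pool
#'
#' Founders are drawn in Hardy-Weinberg proportions at per-marker allele
#' frequencies uniform in `cfg$founder_maf`. Each subsequent non-overlapping
#' generation is formed by sampling, for every offspring, two distinct
#' parents uniformly at random; each parent transmits one allele per locus
#' independently (loci are unlinked, no mutation or selection). Population
#' size stays at `n_founders` until the final generation, which has
#' `n_offspring` individuals and is returned.
#'
#' @param cfg a [sim_config()].
#' @return n_offspring x n_markers dosage matrix (see [genotype_matrix()]).
#' @examples
#' g <- simulate_genotypes(sim_config(n_founders = 10, n_generations = 2,
#'                                    n_offspring = 20, n_markers = 5,
#'                                    seed = 1))
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- cfg$n_markers
  freq <- stats::runif(p, cfg$founder_maf[1L], cfg$founder_maf[2L])
  pop <- matrix(stats::rbinom(cfg$n_founders * p, 2L,
                              rep(freq, each = cfg$n_founders)),
                cfg$n_founders, p)
  for (gen in seq_len(cfg$n_generations)) {
    size <- if (gen == cfg$n_generations) cfg$n_offspring else cfg$n_founders
    par1 <- sample.int(nrow(pop), size, replace = TRUE)
    # second parent distinct from the first
    par2 <- sample.int(nrow(pop) - 1L, size, replace = TRUE)
    par2 <- par2 + (par2 >= par1)
    gam1 <- matrix(stats::rbinom(size * p, 1L, pop[par1, , drop = FALSE] / 2),
                   size, p)
    gam2 <- matrix(stats::rbinom(size * p, 1L, pop[par2, , drop = FALSE] / 2),
                   size, p)
    pop <- gam1 + gam2
  }
  if (all(apply(pop, 2L, function(col) length(unique(col)) == 1L)))
    warning("all simulated markers are monomorphic; increase population ",
            "size or founder allele frequencies")
  genotype_matrix(pop, individual_ids = paste0("ind", seq_len(nrow(pop))),
                  marker_ids = paste0("M", seq_len(p)))
}

#' Simulate phenotypes with additive marker effects
#'
#' Generates \eqn{y = X\beta + e} with \eqn{\mu = 0}: marker effects are
#' drawn iid normal and rescaled so that the realized genetic variance
#' fraction \eqn{\mathrm{var}(X\beta)/\mathrm{var}(y)} matches the target
#' heritability `h2` in expectation (residuals are iid
#' \eqn{N(0, 1 - h2)} and the genetic values are scaled to sample variance
#' `h2`).
#'
#' @param genotypes dosage matrix, e.g. from [simulate_genotypes()].
#' @param h2 target narrow-sense heritability in (0, 1); may also be given
#'   via `cfg`.
#' @param cfg optional [sim_config()]; its `h2` is used if `h2` is missing.
#' @param seed optional integer seed.
#' @return list with `phenotypes` (named vector), `true_effects` (the
#'   rescaled marker effects), `sigma2_beta` (their realized variance
#'   parameter), `sigma2_e` (residual variance `1 - h2`), and
#'   `h2_realized` (sample genetic-variance fraction actually achieved).
#' @export
simulate_phenotypes <- function(genotypes, h2 = NULL, cfg = NULL,
                                seed = NULL) {
  X <- genotype_matrix(genotypes)
  if (is.null(h2)) {
    if (is.null(cfg)) stop("supply h2 or a sim_config")
    h2 <- cfg$h2
  }
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(X)
  beta <- stats::rnorm(p)
  g <- drop(X %*% beta)
  vg <- stats::var(g)
  if (vg == 0)
    stop("genetic variance is zero (all markers effectively monomorphic); ",
         "simulate more polymorphic markers")
  scale <- sqrt(h2 / vg)
  beta <- beta * scale
  g <- g * scale
  sigma2_e <- 1 - h2
  e <- stats::rnorm(nrow(X), 0, sqrt(sigma2_e))
  y <- g + e
  names(y) <- rownames(X)
  list(phenotypes = y,
       true_effects = stats::setNames(beta, colnames(X)),
       sigma2_beta = scale^2, sigma2_e = sigma2_e,
       h2_realized = stats::var(g) / stats::var(y))
}
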