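#' Simulation scenario table
#'
#' Six scenarios varying the number of differentially expressed genes in the
#' 16-gene causal set and the effect-size range (absolute log2 fold change
#' drawn uniformly):
#' S1 (8, U[0.8, 1]), S2 (8, U[1, 3]), S3 (8, U[2, 4]),
#' S4 (12, U[0.8, 1]), S5 (12, U[1, 3]), S6 (12, U[2, 4]).
#'
#' @param tag Scenario tag, "S1".."S6".
#' @return List with \code{n_causal_de} and \code{effect_range}.
#' @export
sim_scenario <- function(tag) {
  grid <- list(S1 = list(8L, c(0.8, 1)), S2 = list(8L, c(1, 3)),
               S3 = list(8L, c(2, 4)), S4 = list(12L, c(0.8, 1)),
               S5 = list(12L, c(1, 3)), S6 = list(12L, c(2, 4)))
  if (!tag %in% names(grid))
    stop("unknown scenario '", tag, "'; use one of ",
         paste(names(grid), collapse = ", "))
  stats::setNames(grid[[tag]], c("n_causal_de", "effect_range"))
}

#' Build a full simulation configuration
#'
#' Defaults reproduce the study design: 1000 genes, 200 samples per class,
#' 100 gene sets of which the first is a 16-gene causal set, baseline
#' log2 means uniform on [3, 10], negative-binomial counts with dispersion
#' 0.15 (variance \eqn{\mu + 0.15 \mu^2}), non-causal set sizes uniform on
#' \{15, ..., 100\}, and no library-size variation (an optional per-sample
#' depth multiplier U[0.5, 2] exercises the normalization path).
#'
#' @param tag Scenario tag "S1".."S6" fixing \code{n_causal_de} and
#'   \code{effect_range}; both can also be given directly.
#' @param seed Integer seed (required for reproducible generation).
#' @param n_genes,n_samples_per_class,n_sets,causal_set_size Design sizes.
#' @param n_causal_de,effect_range Override the scenario values.
#' @param nb_dispersion NB dispersion.
#' @param baseline_log2_mean_range Range of log2 baseline means.
#' @param set_size_range Range of non-causal set sizes (inclusive).
#' @param effect_sign \code{"set"} (default): one association direction is
#'   drawn per causal set and shared by its DE genes, emulating a common
#'   genetic driver of the set's activity; \code{"gene"}: an independent
#'   random sign per gene, which splits the causal signal across both tails
#'   and blinds direction-sensitive statistics such as the signed
#'   Kolmogorov-Smirnov score.
#' @param depth_variation Draw per-sample depth multipliers from U[0.5, 2]?
#' @return List of class \code{"gsa_scenario"}.
#' @export
scenario_config <- function(tag = "S1", seed = 1L, n_genes = 1000L,
                            n_samples_per_class = 200L, n_sets = 100L,
                            causal_set_size = 16L, n_causal_de = NULL,
                            effect_range = NULL, nb_dispersion = 0.15,
                            baseline_log2_mean_range = c(3, 10),
                            set_size_range = c(15L, 100L),
                            effect_sign = c("set", "gene"),
                            depth_variation = FALSE) {
  effect_sign <- match.arg(effect_sign)
  sc <- sim_scenario(tag)
  if (is.null(n_causal_de)) n_causal_de <- sc$n_causal_de
  if (is.null(effect_range)) effect_range <- sc$effect_range
  stopifnot(n_causal_de <= causal_set_size,
            effect_range[1L] < effect_range[2L], all(effect_range > 0),
            nb_dispersion > 0, causal_set_size < n_genes,
            set_size_range[1L] >= 1L,
            set_size_range[2L] <= n_genes - causal_set_size)
  structure(list(tag = tag, seed = as.integer(seed),
                 n_genes = as.integer(n_genes),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 n_sets = as.integer(n_sets),
                 causal_set_size = as.integer(causal_set_size),
                 n_causal_de = as.integer(n_causal_de),
                 effect_range = effect_range,
                 nb_dispersion = nb_dispersion,
                 baseline_log2_mean_range = baseline_log2_mean_range,
                 set_size_range = set_size_range,
                 effect_sign = effect_sign,
                 depth_variation = isTRUE(depth_variation)),
            class = "gsa_scenario")
}

#' Generate one simulated dataset
#'
#' Counts are negative-binomial with gene-specific baseline mean
#' \eqn{\mu_g} (\eqn{\log_2 \mu_g} uniform over the configured range) and
#' fixed dispersion. For each differentially expressed causal gene an effect
#' \eqn{\beta} is drawn from the scenario's range and the comparison-class
#' mean set to \eqn{\mu_g 2^{\pm\beta}} (so \eqn{\beta} is the absolute log2
#' fold change); the sign is drawn once per causal set by default (see
#' \code{effect_sign} in \code{\link{scenario_config}}). The first gene set is the
#' causal set; the remaining sets draw only from non-causal genes (a
#' non-causal gene may appear in several sets). Bit-reproducible given the
#' configured seed.
#'
#' @param config A \code{\link{scenario_config}} object.
#' @return List of class \code{"gsa_simdata"}: \code{counts} (matrix),
#'   \code{labels} (factor, levels A then B; B carries the fold changes),
#'   \code{sets} (named list, first set causal), \code{causal_set_name},
#'   and \code{de_genes} (data frame gene / log2fc).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "gsa_scenario"))
  with_seed(config$seed, function() {
    G <- config$n_genes
    n <- config$n_samples_per_class
    gene_ids <- sprintf("GENE_%04d", seq_len(G))
    sample_ids <- sprintf("SAMP_%03d", seq_len(2L * n))
    mu <- 2^stats::runif(G, config$baseline_log2_mean_range[1L],
                         config$baseline_log2_mean_range[2L])
    causal_idx <- seq_len(config$causal_set_size)
    de_idx <- sort(sample(causal_idx, config$n_causal_de))
    beta <- stats::runif(config$n_causal_de, config$effect_range[1L],
                         config$effect_range[2L])
    eps <- if (identical(config$effect_sign, "gene"))
      sample(c(-1, 1), config$n_causal_de, replace = TRUE)
    else rep(sample(c(-1, 1), 1L), config$n_causal_de)
    mu2 <- mu
    mu2[de_idx] <- mu[de_idx] * 2^(eps * beta)
    size <- 1 / config$nb_dispersion
    depth <- if (config$depth_variation)
      stats::runif(2L * n, 0.5, 2) else rep(1, 2L * n)
    counts <- matrix(0L, G, 2L * n, dimnames = list(gene_ids, sample_ids))
    for (s in seq_len(2L * n)) {
      m_s <- if (s <= n) mu else mu2
      counts[, s] <- stats::rnbinom(G, size = size, mu = m_s * depth[s])
    }
    labels <- factor(rep(c("A", "B"), each = n), levels = c("A", "B"))
    set_names <- sprintf("SET_%03d", seq_len(config$n_sets))
    null_pool <- setdiff(seq_len(G), causal_idx)
    sets <- vector("list", config$n_sets)
    sets[[1L]] <- gene_ids[causal_idx]
    for (i in seq_len(config$n_sets)[-1L]) {
      k <- sample(seq(config$set_size_range[1L], config$set_size_range[2L]),
                  1L)
      sets[[i]] <- gene_ids[sample(null_pool, k)]
    }
    names(sets) <- set_names
    attr(sets, "description") <- stats::setNames(
      c("causal", rep("null", config$n_sets - 1L)), set_names)
    structure(list(counts = counts, labels = labels, sets = sets,
                   causal_set_name = set_names[1L],
                   de_genes = data.frame(gene = gene_ids[de_idx],
                                         log2fc = eps * beta,
                                         stringsAsFactors = FALSE),
                   config = config),
              class = "gsa_simdata")
  })
}

#' Generate replicate datasets for a scenario
#'
#' Draws one sub-seed per replicate from the master seed and either returns
#' the datasets or, if \code{FUN} is given, applies it to each dataset in
#' turn and returns the list of results (so large replicate sets can be
#' processed without holding all count matrices in memory).
#'
#' @param tag Scenario tag "S1".."S6".
#' @param n_replicates Number of replicates.
#' @param seed Master integer seed.
#' @param FUN Optional function applied to each \code{gsa_simdata}.
#' @param ... Passed to \code{\link{scenario_config}} (design overrides).
#' @return List of datasets, or of \code{FUN} results.
#' @export
simulate_replicates <- function(tag, n_replicates, seed = 1L, FUN = NULL,
                                ...) {
  stopifnot(n_replicates >= 1L)
  rep_seeds <- with_seed(seed, function()
    sample.int(.Machine$integer.max, n_replicates))
  lapply(seq_len(n_replicates), function(i) {
    d <- simulate_dataset(scenario_config(tag, seed = rep_seeds[i], ...))
    if (is.null(FUN)) d else FUN(d)
  })
}
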