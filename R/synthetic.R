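#' Configuration for the synthetic volvocine-like data generator
#'
#' Defaults emulate the comparative dataset the package is built to
#' analyze: 18 differentiated volvocine species whose cell numbers span
#' roughly 10^2 to 5 x 10^4, whose germ fraction follows a power law
#' pg = 10^a * N^b with exponent b near -1.2 plus lognormal scatter, and
#' whose traits covary through shared phylogeny.
#'
#' The intercept (a = 1.57) pins the scaling line through the Volvox
#' aureus point (N = 2048, pg = 8/2048). The noise SD (0.05 on log10 pg)
#' is a calibration choice producing a contrasts-regression r^2 near 0.95
#' on typical draws. log10
#' cell number evolves by Brownian motion on a Yule tree, matching the
#' assumption of the contrasts analysis exactly, so parameter recovery
#' tests the contrasts engine, not model misspecification.
#'
#' @param n_species number of tips (>= 4).
#' @param birth_rate Yule (pure-birth) speciation rate.
#' @param sigma_logN Brownian-motion SD of log10 cell number per unit
#'   branch length.
#' @param logN_root root state of log10 cell number.
#' @param logN_range admissible span of log10 cell number; tip values are
#'   clamped into it (clamping flagged in the output metadata).
#' @param true_exponent ground-truth scaling exponent b.
#' @param intercept_a log10 proportionality constant a.
#' @param noise_sd SD of the lognormal noise on pg (log10 units).
#' @param integer_counts round cell and germ counts to integers as in real
#'   species records (default). \code{FALSE} keeps continuous traits, under
#'   which a noise-free draw recovers the exponent exactly; the gap between
#'   the two quantifies rounding bias.
#' @param seed integer seed.
#' @return A \code{"volvocine_config"} list.
#' @export
volvocine_config <- function(n_species = 18,
                             birth_rate = 1,
                             sigma_logN = 0.5,
                             logN_root = log10(2000),
                             logN_range = c(2, log10(5e4)),
                             true_exponent = -1.2,
                             intercept_a = 1.57,
                             noise_sd = 0.05,
                             integer_counts = TRUE,
                             seed = NULL) {
  stopifnot(n_species >= 4, birth_rate > 0, sigma_logN > 0,
            length(logN_range) == 2L, logN_range[1] < logN_range[2],
            noise_sd >= 0)
  structure(list(n_species = as.integer(n_species), birth_rate = birth_rate,
                 sigma_logN = sigma_logN, logN_root = logN_root,
                 logN_range = logN_range, true_exponent = true_exponent,
                 intercept_a = intercept_a, noise_sd = noise_sd,
                 integer_counts = isTRUE(integer_counts), seed = seed),
            class = "volvocine_config")
}

#' Simulate a Yule phylogeny of synthetic species
#'
#' Pure-birth ultrametric tree with \code{n_species} tips, labelled
#' \code{syn_sp_01, ...} (synthetic stand-ins, not real taxa).
#'
#' @param config a [volvocine_config]; its \code{seed}, if set, makes the
#'   tree reproducible.
#' @return An \code{ape::phylo} tree with positive branch lengths.
#' @export
generate_tree <- function(config = volvocine_config()) {
  stopifnot(inherits(config, "volvocine_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tree <- ape::rphylo(config$n_species, birth = config$birth_rate, death = 0)
  tree$tip.label <- sprintf("syn_sp_%02d", seq_len(config$n_species))
  tree
}

#' Simulate species traits on a phylogeny
#'
#' log10 cell number evolves by Brownian motion from the root state;
#' tip values are clamped into \code{logN_range}. Germ fraction follows
#' log10 pg = a + b * log10 N + Normal(0, noise_sd), resampled per species
#' (up to 100 times, then truncated with a flag) so that counts respect
#' 1 <= n_germ <= n_cells after integer rounding, with n_germ floored at
#' one germ cell.
#'
#' @param tree phylogeny from [generate_tree] (tip labels become species
#'   names).
#' @param config a [volvocine_config]. Note the RNG continues from the
#'   current state; call [generate_volvocine_data] for end-to-end seeding.
#' @return A [species_table] with attribute \code{"truth"} recording the
#'   generating parameters and any truncation.
#' @export
generate_traits <- function(tree, config = volvocine_config()) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "volvocine_config"))
  logN <- ape::rTraitCont(tree, model = "BM", sigma = config$sigma_logN,
                          root.value = config$logN_root)
  logN <- pmin(pmax(logN, config$logN_range[1]), config$logN_range[2])
  n_cells <- if (config$integer_counts) round(10^logN) else 10^logN

  truncated <- character(0)
  pg <- numeric(length(logN))
  for (i in seq_along(logN)) {
    mu <- config$intercept_a + config$true_exponent * log10(n_cells[i])
    ok <- FALSE
    for (try in seq_len(100L)) {
      cand <- 10^(mu + stats::rnorm(1L, 0, config$noise_sd))
      if (cand <= 1 && cand >= 1 / n_cells[i]) { ok <- TRUE; break }
    }
    if (!ok) {
      cand <- min(1, max(1 / n_cells[i], 10^mu))
      truncated <- c(truncated, tree$tip.label[i])
    }
    pg[i] <- cand
  }
  n_germ <- if (config$integer_counts) pmax(1, round(pg * n_cells))
            else pmax(1, pg * n_cells)
  n_germ <- pmin(n_germ, n_cells)
  out <- species_table(data.frame(name = tree$tip.label,
                                  n_cells = n_cells, n_germ = n_germ,
                                  stringsAsFactors = FALSE))
  attr(out, "truth") <- list(true_exponent = config$true_exponent,
                             intercept_a = config$intercept_a,
                             noise_sd = config$noise_sd,
                             logN = unname(logN),
                             truncated = truncated)
  out
}

#' Generate a complete synthetic comparative dataset
#'
#' Tree plus species table with known ground truth, reproducible from the
#' config seed.
#'
#' @param config a [volvocine_config].
#' @return List with \code{tree}, \code{species} (a [species_table]),
#'   \code{truth} (generating parameters) and \code{config}.
#' @examples
#' ds <- generate_volvocine_data(volvocine_config(seed = 42))
#' range(ds$species$n_cells)
#' @export
generate_volvocine_data <- function(config = volvocine_config()) {
  stopifnot(inherits(config, "volvocine_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_noseed <- config; cfg_noseed$seed <- NULL
  tree <- generate_tree(cfg_noseed)
  species <- generate_traits(tree, cfg_noseed)
  list(tree = tree, species = species, truth = attr(species, "truth"),
       config = config)
}

#' Write a synthetic dataset to disk
#'
#' Newick tree, CSV species table, and a JSON metadata sidecar with the
#' generating parameters (ground truth), so a dataset can be round-tripped
#' through the comparative readers.
#'
#' @param dataset output of [generate_volvocine_data].
#' @param prefix path prefix; writes \code{<prefix>.nwk},
#'   \code{<prefix>.csv}, \code{<prefix>.json}.
#' @return Invisibly, the three paths written.
#' @export
write_volvocine_data <- function(dataset, prefix) {
  paths <- paste0(prefix, c(".nwk", ".csv", ".json"))
  ape::write.tree(dataset$tree, file = paths[1])
  utils::write.csv(dataset$species[c("name", "n_cells", "n_germ")],
                   paths[2], row.names = FALSE, quote = FALSE)
  meta <- c(dataset$truth[c("true_exponent", "intercept_a", "noise_sd",
                            "truncated")],
            list(n_species = length(dataset$tree$tip.label),
                 seed = dataset$config$seed))
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
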