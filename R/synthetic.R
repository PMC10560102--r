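# Self-contained synthetic inputs: congeneric SMILES series with controlled
# fingerprint similarity, a small SMILES+logBB dataset for end-to-end runs,
# and descriptor tables with block-correlated features and a known
# linear-plus-noise logBB generative model with an analytic R-squared
# ceiling. Everything is reproducible from an integer seed.

#' Generate congeneric SMILES series
#'
#' Chemically trivial homologous series: within one series adjacent members
#' share most circular-fingerprint environments (high Tanimoto similarity,
#' giving deduplication its discard cases), while cross-series pairs are
#' dissimilar (the keep cases).
#'
#' @param kind `"alkanes"` (hexane upward), `"alcohols"` (hexanol upward),
#'   or `"mixed"` (alkanes, alcohols and alkylbenzenes interleaved).
#' @param n Number of SMILES to return (>= 1).
#' @return Character vector of `n` valid SMILES.
#' @export
make_smiles_series <- function(kind = c("alkanes", "alcohols", "mixed"), n) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(n), n >= 1)
  n <- as.integer(n)
  alk <- function(m) vapply(seq_len(m), function(i) strrep("C", 5L + i),
                            character(1))
  alc <- function(m) paste0(alk(m), "O")
  aro <- function(m) vapply(seq_len(m), function(i)
    paste0(strrep("C", i - 1L), "c1ccccc1"), character(1))
  out <- switch(kind,
    alkanes = alk(n),
    alcohols = alc(n),
    mixed = {
      m <- ceiling(n / 3)
      series <- list(alk(m), alc(m), aro(m))
      interleaved <- as.character(t(cbind(series[[1]], series[[2]], series[[3]])))
      interleaved[seq_len(n)]
    })
  out
}

# Structurally diverse small molecules from a scaffold x substituent
# product, ordered so neighbouring entries change both factors. Unlike the
# homologous series, these survive Tanimoto deduplication largely intact.
.diverse_smiles <- function(n) {
  scaffolds <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "c1ccoc1", "c1ccsc1",
                 "C1CCNCC1", "C1CCOCC1", "c1ccc2ccccc2c1", "C1CCCCCC1",
                 "C1CC1")
  prefixes <- c("", "C", "CCC", "O", "CO", "N", "CN(C)", "Cl", "Br",
                "OC(=O)", "FC(F)(F)", "N#C", "CS")
  combos <- as.vector(t(outer(prefixes, scaffolds, paste0)))
  if (n > length(combos))
    bbb_error("bbbqsar_schema_error",
              sprintf("at most %d diverse molecules available", length(combos)))
  combos[seq_len(n)]
}

#' Generate a small SMILES+logBB dataset for end-to-end runs
#'
#' Builds a structurally diverse set of small molecules (ring scaffolds
#' crossed with common substituents), computes its real 2D descriptors, and
#' assigns a synthetic logBB from a fixed linear rule on lipophilicity,
#' molecular weight and polar surface area plus Gaussian noise — echoing
#' the qualitative physics of barrier permeation (lipophilic helps, size
#' and polarity hurt) and spreading values across the conventional
#' permeability cutoff of -1 so both classes are populated.
#'
#' @param n Number of compounds (at most 130).
#' @param seed Integer seed for the noise.
#' @param noise_sd Gaussian noise sd in logBB units.
#' @return data.frame with columns `id`, `smiles`, `logbb`, ready to be
#'   written to CSV and fed to [run_pipeline()].
#' @export
make_molecule_dataset <- function(n = 60, seed = 1, noise_sd = 0.3) {
  smiles <- .diverse_smiles(n)
  desc <- compute_descriptors(smiles)
  set.seed(seed)
  logbb <- 0.25 * desc[, "logP"] - 0.012 * desc[, "MW"] -
    0.04 * desc[, "TPSA"] + 0.8 + stats::rnorm(n, 0, noise_sd)
  data.frame(id = sprintf("syn_%04d", seq_len(n)), smiles = smiles,
             logbb = as.numeric(logbb), stringsAsFactors = FALSE)
}

#' Noise level for a target out-of-sample R-squared ceiling
#'
#' For `y = X beta + e` with independent standard-normal signal features,
#' the best attainable R-squared is
#' `sum(beta^2) / (sum(beta^2) + noise_sd^2)`; this inverts that relation.
#'
#' @param coefficients Signal coefficients `beta`.
#' @param ceiling Target R-squared ceiling in (0, 1).
#' @return The Gaussian noise sd achieving the ceiling.
#' @export
noise_sd_for_ceiling <- function(coefficients, ceiling) {
  stopifnot(ceiling > 0, ceiling < 1)
  sqrt(sum(coefficients^2) * (1 - ceiling) / ceiling)
}

#' Generate a descriptor table with block-redundant features and known signal
#'
#' Each signal feature is a standard-normal column `z_j`; its block also
#' contains `clones_per_block` noisy copies `rho * z_j + sqrt(1-rho^2) * e`,
#' so every clone correlates with its base at exactly `rho` (clone-clone
#' correlation is `rho^2`). Independent standard-normal noise features are
#' appended. The response is
#' `y = intercept + sum_j beta_j z_j + N(0, noise_sd)`, giving the analytic
#' out-of-sample R-squared ceiling `1 - noise_sd^2 / var(y)` =
#' `sum(beta^2) / (sum(beta^2) + noise_sd^2)`.
#'
#' @param n_compounds Rows to generate.
#' @param n_signal_features Number of signal blocks.
#' @param clones_per_block Noisy copies added per block.
#' @param intra_block_corr Clone-base correlation `rho` in \[0, 1\].
#' @param noise_sd Response noise sd (logBB units, >= 0).
#' @param coefficients Signal coefficients; length `n_signal_features`.
#'   Default: a decreasing sequence 1, 0.8, 0.6, ...
#' @param n_noise_features Unrelated standard-normal columns.
#' @param intercept Response offset (centers the logBB envelope).
#' @param seed Integer seed; same seed, byte-identical dataset.
#' @return List with `x` (numeric matrix, named columns `sigJ`,
#'   `sigJ_cloneC`, `noiseI`), `y` (response), and `truth` (list: `blocks`
#'   — block membership, `coefficients`, `noise_sd`, `intercept`,
#'   `intra_block_corr`, `r2_ceiling`, `seed`).
#' @export
make_regression_dataset <- function(n_compounds, n_signal_features = 3,
                                    clones_per_block = 10,
                                    intra_block_corr = 0.95,
                                    noise_sd = 0.5,
                                    coefficients = NULL,
                                    n_noise_features = 5,
                                    intercept = -0.5, seed = 42) {
  coefficients <- coefficients %||%
    seq(1, by = -0.2, length.out = n_signal_features)
  if (length(coefficients) != n_signal_features)
    bbb_error("bbbqsar_schema_error",
              "coefficients length must equal n_signal_features")
  if (intra_block_corr < 0 || intra_block_corr > 1)
    bbb_error("bbbqsar_schema_error", "intra_block_corr must be in [0, 1]")
  if (noise_sd < 0)
    bbb_error("bbbqsar_schema_error", "noise_sd must be >= 0")
  stopifnot(n_compounds >= 2, n_signal_features >= 1, clones_per_block >= 0,
            n_noise_features >= 0)
  set.seed(seed)
  n <- as.integer(n_compounds)
  rho <- intra_block_corr
  cols <- list(); blocks <- list()
  z <- matrix(stats::rnorm(n * n_signal_features), n, n_signal_features)
  for (j in seq_len(n_signal_features)) {
    base_name <- sprintf("sig%d", j)
    block_names <- base_name
    cols[[base_name]] <- z[, j]
    if (clones_per_block > 0) {
      for (cidx in seq_len(clones_per_block)) {
        nm <- sprintf("sig%d_clone%02d", j, cidx)
        cols[[nm]] <- rho * z[, j] + sqrt(1 - rho^2) * stats::rnorm(n)
        block_names <- c(block_names, nm)
      }
    }
    blocks[[base_name]] <- block_names
  }
  if (n_noise_features > 0) {
    for (i in seq_len(n_noise_features))
      cols[[sprintf("noise%02d", i)]] <- stats::rnorm(n)
  }
  x <- do.call(cbind, cols)
  rownames(x) <- sprintf("syn_%05d", seq_len(n))
  y <- intercept + as.numeric(z %*% coefficients) +
    stats::rnorm(n, 0, noise_sd)
  sig_var <- sum(coefficients^2)
  r2_ceiling <- if (sig_var + noise_sd^2 == 0) NA_real_ else
    sig_var / (sig_var + noise_sd^2)
  list(x = x, y = y,
       truth = list(blocks = blocks, coefficients = coefficients,
                    noise_sd = noise_sd, intercept = intercept,
                    intra_block_corr = rho, r2_ceiling = r2_ceiling,
                    seed = seed))
}
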