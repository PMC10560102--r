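# Shared fixtures and independent oracles for the test suite.

# Brute-force Tanimoto over an explicit bit loop: the independent oracle the
# vectorized implementation is checked against.
tanimoto_bitloop <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- 0; nb <- 0; nc <- 0
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
    if (a[i] && b[i]) nc <- nc + 1
  }
  if (na + nb - nc == 0) return(0)
  nc / (na + nb - nc)
}

random_fp <- function(n_bits = 1024L, density = 0.05) {
  stats::runif(n_bits) < density
}

write_tmp_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# A small curated SMILES+logBB CSV on disk (memoized per test run).
local({
  cache <- new.env(parent = emptyenv())
  fixture_molecule_csv <<- function(n = 40, seed = 1) {
    key <- paste0("mol", n, "_", seed)
    if (is.null(cache[[key]])) {
      d <- make_molecule_dataset(n, seed = seed)
      path <- tempfile(fileext = ".csv")
      utils::write.csv(d, path, row.names = FALSE)
      cache[[key]] <- path
    }
    cache[[key]]
  }
})
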