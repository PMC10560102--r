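# Fingerprints, Tanimoto similarity, deduplication and reference screening.

test_that("fingerprints are deterministic and notation-invariant", {
  f1 <- morgan_fingerprint("CCO")
  f2 <- morgan_fingerprint("CCO")
  f3 <- morgan_fingerprint(canonicalize_smiles("OCC"))
  expect_identical(f1$bits, f2$bits)
  expect_identical(f1$bits, f3$bits)
  expect_length(f1$bits, 1024L)
  expect_equal(f1$n_on, sum(f1$bits))
  expect_gte(morgan_fingerprint("C")$n_on, 1L)
})

test_that("tanimoto matches Eq.-style closed forms on hand-built vectors", {
  a <- logical(16); a[c(1, 3, 5, 7)] <- TRUE   # N_a = 4
  b <- logical(16); b[c(1, 3, 8, 9)] <- TRUE   # N_b = 4, N_c = 2
  expect_equal(tanimoto(a, b), 2 / (4 + 4 - 2))
  expect_equal(tanimoto(a, a), 1.0)
  d <- logical(16); d[c(10, 12)] <- TRUE
  expect_equal(tanimoto(a, d), 0.0)
  expect_equal(tanimoto(logical(16), logical(16)), 0)  # 0/0 defined as 0
  expect_error(tanimoto(a, logical(8)), class = "bbbqsar_schema_error")
})

test_that("tanimoto is symmetric and agrees with the bit-loop oracle", {
  set.seed(11)
  for (i in 1:25) {
    a <- random_fp(); b <- random_fp()
    expect_equal(tanimoto(a, b), tanimoto_bitloop(a, b), tolerance = 1e-15)
    expect_identical(tanimoto(a, b), tanimoto(b, a))
  }
})

test_that("deduplicate keeps leaders, discards similars, partitions input", {
  smi <- c("CCO", "OCC", "c1ccccc1")  # first two identical molecules
  ds <- data.frame(id = c("a", "b", "c"), smiles_raw = smi,
                   smiles_canonical = canonicalize_smiles(smi),
                   logbb = c(1, 2, 3))
  dd <- deduplicate(ds)
  expect_equal(dd$kept$id, c("a", "c"))
  drop_b <- dd$decisions[dd$decisions$id == "b", ]
  expect_equal(drop_b$t, 1.0)
  expect_equal(drop_b$matched_id, "a")
  expect_equal(sum(dd$decisions$kept) + sum(!dd$decisions$kept), nrow(ds))
})

test_that("dissimilar molecules are both kept and similarity at cutoff keeps", {
  # unrelated scaffolds: Tanimoto verified <= 0.85 by the fingerprint oracle
  smi <- c("C", "c1ccccc1")
  t <- tanimoto(morgan_fingerprint(smi[1]), morgan_fingerprint(smi[2]))
  expect_lte(t, 0.85)
  ds <- data.frame(id = c("m", "b"), smiles_raw = smi,
                   smiles_canonical = canonicalize_smiles(smi),
                   logbb = c(0, 0))
  dd <- deduplicate(ds)
  expect_equal(nrow(dd$kept), 2L)
  # boundary: similarity exactly at the cutoff is kept (strict ">" discards)
  dd2 <- deduplicate(ds, cutoff = t)
  expect_equal(nrow(dd2$kept), 2L)
})

test_that("deduplicate is idempotent and handles empty input", {
  smi <- make_smiles_series("mixed", 12)
  ds <- data.frame(id = sprintf("s%02d", seq_along(smi)), smiles_raw = smi,
                   smiles_canonical = canonicalize_smiles(smi),
                   logbb = 0)
  dd <- deduplicate(ds)
  dd2 <- deduplicate(dd$kept)
  expect_equal(dd2$kept$id, dd$kept$id)
  expect_true(all(dd2$decisions$kept))
  empty <- deduplicate(ds[0, ])
  expect_equal(nrow(empty$kept), 0L)
})

test_that("screening removes near-duplicates of the reference and only those", {
  ref_smi <- c("CCO", "c1ccccc1")
  ref <- data.frame(id = c("r1", "r2"), smiles_raw = ref_smi,
                    smiles_canonical = canonicalize_smiles(ref_smi),
                    logbb = 0)
  q_smi <- c("OCC", "C1CCNCC1")  # first is ethanol again
  q <- data.frame(id = c("q1", "q2"), smiles_raw = q_smi,
                  smiles_canonical = canonicalize_smiles(q_smi),
                  logbb = NA_real_)
  kept <- screen_against_reference(q, ref)
  expect_equal(kept$id, "q2")
  sim <- attr(kept, "similarity")
  expect_equal(sim$t[sim$id == "q1"], 1.0)
  # empty reference keeps everything, with a warning
  expect_warning(all_kept <- screen_against_reference(q, ref[0, ]))
  expect_equal(nrow(all_kept), 2L)
  # empty query returns empty
  expect_equal(nrow(screen_against_reference(q[0, ], ref)), 0L)
})
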