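# Circular (Morgan) fingerprints, Tanimoto similarity, and similarity-based
# dataset curation: leader-style deduplication within a dataset and screening
# of a query/test set against a training reference, both at cutoff 0.85.
#
# The fingerprint is an ECFP4-style circular fingerprint computed over the
# OpenBabel-parsed molecular graph: per-atom invariants (element, graph
# degree, bond-order sum, implicit hydrogen count, formal charge) are
# iteratively rehashed with sorted (bond order, neighbour invariant) tuples
# up to the given radius, and every environment identifier is folded into a
# fixed-length bit vector. Deterministic: same canonical SMILES, same bits.

# 26-bit polynomial string hash; stays in exact double-precision integers.
.hash_string <- function(s, mod = 67108859) {
  h <- 5381
  for (x in utf8ToInt(s)) h <- (h * 31 + x) %% mod
  h
}

# Fingerprint one molecular graph (from .molgraphs).
.fp_one <- function(g, radius, n_bits) {
  nb <- g$natoms
  sym <- g$sym; charge <- g$charge; nh <- g$nh; valsum <- g$valsum
  a1 <- g$a1; a2 <- g$a2; ord <- g$ord
  deg <- tabulate(c(a1, a2), nbins = nb)
  adj <- vector("list", nb)
  for (i in seq_along(a1)) {
    adj[[a1[i]]] <- c(adj[[a1[i]]], i)
    adj[[a2[i]]] <- c(adj[[a2[i]]], i)
  }
  inv <- vapply(seq_len(nb), function(i)
    .hash_string(paste(sym[i], deg[i], valsum[i], nh[i], charge[i], sep = "|")),
    numeric(1))
  feats <- inv
  if (radius > 0L && nb > 1L) {
    for (r in seq_len(radius)) {
      newinv <- inv
      for (i in seq_len(nb)) {
        bidx <- adj[[i]]
        if (length(bidx) == 0L) next
        other <- ifelse(a1[bidx] == i, a2[bidx], a1[bidx])
        parts <- sort(paste0(ord[bidx], ":", inv[other]))
        newinv[i] <- .hash_string(
          paste(inv[i], paste(parts, collapse = ","), sep = "|"))
      }
      inv <- newinv
      feats <- c(feats, inv)
    }
  }
  bits <- logical(n_bits)
  bits[(feats %% n_bits) + 1L] <- TRUE
  bits
}

.fp_bits <- function(x) {
  if (inherits(x, "bbb_fingerprint")) return(x$bits)
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  bbb_error("bbbqsar_schema_error", "not a fingerprint or bit vector")
}

# Fingerprint a character vector of SMILES into an n x n_bits logical matrix.
.fp_matrix <- function(smiles, radius = 2L, n_bits = 1024L) {
  if (length(smiles) == 0L)
    return(matrix(logical(0), nrow = 0L, ncol = n_bits))
  ok <- vapply(smiles, .smiles_syntax_ok, logical(1), USE.NAMES = FALSE)
  graphs <- if (all(ok)) .molgraphs(smiles) else vector("list", length(smiles))
  bad <- vapply(graphs, is.null, logical(1))
  if (any(bad))
    bbb_error("bbbqsar_internal_error",
              sprintf("unparseable SMILES reached fingerprinting: %s",
                      paste(smiles[bad], collapse = ", ")))
  t(vapply(graphs, function(g) .fp_one(g, radius, n_bits), logical(n_bits)))
}

#' Compute a circular (Morgan) fingerprint
#'
#' ECFP4-equivalent circular fingerprint: radius 2, folded to 1024 bits.
#' Deterministic — two SMILES of the same molecule give identical bits.
#'
#' @param x A SMILES string or one row of a compound dataset.
#' @param radius Neighbourhood radius (2 approximates ECFP4).
#' @param n_bits Folded fingerprint length.
#' @return Object of class `bbb_fingerprint`: list with `bits` (logical
#'   vector of length `n_bits`) and `n_on` (number of set bits).
#' @export
morgan_fingerprint <- function(x, radius = 2L, n_bits = 1024L) {
  smiles <- if (is.data.frame(x)) x$smiles_canonical[1L] else as.character(x)[1L]
  m <- .fp_matrix(smiles, radius, n_bits)
  structure(list(bits = m[1L, ], n_on = sum(m[1L, ]), smiles = smiles,
                 radius = radius, n_bits = n_bits),
            class = "bbb_fingerprint")
}

#' @export
print.bbb_fingerprint <- function(x, ...) {
  cat(sprintf("<bbb_fingerprint> %d bits, %d on (%s)\n",
              length(x$bits), x$n_on, x$smiles))
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' `T = N_c / (N_a + N_b - N_c)` where `N_a`, `N_b` count on-bits in each
#' fingerprint and `N_c` the shared on-bits. Symmetric, in \[0, 1\]. Two
#' all-zero fingerprints are defined to have similarity 0.
#'
#' @param a,b Fingerprints (from [morgan_fingerprint()]) or equal-length
#'   bit vectors (logical or 0/1 numeric).
#' @return Numeric scalar in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  ba <- .fp_bits(a); bb <- .fp_bits(b)
  if (length(ba) != length(bb))
    bbb_error("bbbqsar_schema_error", "fingerprint lengths differ")
  nc <- sum(ba & bb)
  denom <- sum(ba) + sum(bb) - nc
  if (denom == 0) return(0)
  nc / denom
}

# Tanimoto of one bit vector against the rows of a bit matrix.
.tanimoto_vs_matrix <- function(bits, m, n_on_rows) {
  if (nrow(m) == 0L) return(numeric(0))
  inter <- as.numeric(m %*% bits)
  denom <- n_on_rows + sum(bits) - inter
  t <- ifelse(denom == 0, 0, inter / denom)
  t
}

#' Deduplicate a compound dataset by Tanimoto similarity
#'
#' Leader-style greedy pass in input order: a compound is kept iff its
#' Tanimoto similarity to every previously kept compound is at most the
#' cutoff; a strictly greater similarity discards it (similarity of exactly
#' the cutoff keeps). Deterministic for a fixed input order. Molecules with
#' all-zero fingerprints are flagged in the decisions table.
#'
#' @param records Compound dataset (see [read_dataset()]).
#' @param cutoff Tanimoto cutoff; default 0.85.
#' @param radius,n_bits Fingerprint parameters.
#' @return List with `kept` (subset of `records`, all pairwise similarities
#'   <= cutoff) and `decisions` (data.frame: `id`, `matched_id` — the most
#'   similar previously kept compound, `t`, `kept`, `zero_fp`).
#' @export
deduplicate <- function(records, cutoff = 0.85, radius = 2L, n_bits = 1024L) {
  n <- nrow(records)
  if (n == 0L)
    return(list(kept = records,
                decisions = data.frame(id = character(0),
                                       matched_id = character(0),
                                       t = numeric(0), kept = logical(0),
                                       zero_fp = logical(0))))
  m <- .fp_matrix(records$smiles_canonical, radius, n_bits)
  n_on <- rowSums(m)
  keep <- logical(n)
  matched <- rep(NA_character_, n)
  tmax <- rep(NA_real_, n)
  kept_idx <- integer(0)
  for (i in seq_len(n)) {
    if (length(kept_idx) == 0L) {
      keep[i] <- TRUE
    } else {
      t <- .tanimoto_vs_matrix(m[i, ], m[kept_idx, , drop = FALSE],
                               n_on[kept_idx])
      j <- which.max(t)
      matched[i] <- records$id[kept_idx[j]]
      tmax[i] <- t[j]
      keep[i] <- t[j] <= cutoff
    }
    if (keep[i]) kept_idx <- c(kept_idx, i)
  }
  decisions <- data.frame(id = records$id, matched_id = matched, t = tmax,
                          kept = keep, zero_fp = n_on == 0,
                          stringsAsFactors = FALSE)
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, decisions = decisions)
}

#' Screen a query set against a reference set by Tanimoto similarity
#'
#' Keeps each query compound iff its maximum Tanimoto similarity over the
#' reference set is at most the cutoff — the leakage filter applied to an
#' independent test set against the training compounds. The reference is
#' never modified.
#'
#' @param query,reference Compound datasets (see [read_dataset()]).
#' @param cutoff Tanimoto cutoff; default 0.85.
#' @param radius,n_bits Fingerprint parameters.
#' @return The kept query rows; `attr(,"similarity")` holds a data.frame
#'   with each query's max similarity and nearest reference id.
#' @export
screen_against_reference <- function(query, reference, cutoff = 0.85,
                                     radius = 2L, n_bits = 1024L) {
  if (nrow(query) == 0L) {
    attr(query, "similarity") <- data.frame(id = character(0),
                                            nearest_id = character(0),
                                            t = numeric(0), kept = logical(0))
    return(query)
  }
  if (nrow(reference) == 0L) {
    warning("empty reference set: all query compounds kept")
    attr(query, "similarity") <- data.frame(id = query$id,
                                            nearest_id = NA_character_,
                                            t = NA_real_, kept = TRUE,
                                            stringsAsFactors = FALSE)
    return(query)
  }
  mq <- .fp_matrix(query$smiles_canonical, radius, n_bits)
  mr <- .fp_matrix(reference$smiles_canonical, radius, n_bits)
  n_on_r <- rowSums(mr)
  tmax <- numeric(nrow(query)); nearest <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    t <- .tanimoto_vs_matrix(mq[i, ], mr, n_on_r)
    j <- which.max(t)
    tmax[i] <- t[j]; nearest[i] <- reference$id[j]
  }
  keep <- tmax <= cutoff
  out <- query[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "similarity") <- data.frame(id = query$id, nearest_id = nearest,
                                        t = tmax, kept = keep,
                                        stringsAsFactors = FALSE)
  out
}
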