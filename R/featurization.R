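# 2D molecular descriptors, pruning of uninformative columns, and standard
# scaling. The descriptor table is a plain numeric matrix: one row per
# compound (rownames = compound ids), one named column per descriptor.
# Descriptors that fail to compute are NA, never silent zeros; pruning
# removes any column containing a missing or non-finite entry.

# Standard atomic masses and default valences for graph-based molecular
# weight (implicit hydrogens filled to the default valence).
.ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, Si = 28.085, P = 30.974, S = 32.06,
                  Cl = 35.45, Br = 79.904, I = 126.904, Na = 22.99,
                  K = 39.098, Li = 6.94, Ca = 40.078, Mg = 24.305)
.DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1)

.graph_mw <- function(g) {
  mass <- .ATOMIC_MASS[g$sym]
  if (anyNA(mass)) return(NA_real_)
  sum(mass) + sum(g$nh) * .ATOMIC_MASS[["H"]]
}

# Per-molecule constitutional/topological descriptors from the molecular
# graph (see .molgraphs).
.graph_descriptors <- function(g) {
  sym <- g$sym; ord <- g$ord
  deg <- tabulate(c(g$a1, g$a2), nbins = g$natoms)
  heavy <- sym != "H"
  hal <- sym %in% c("F", "Cl", "Br", "I")
  het <- heavy & !(sym %in% c("C"))
  c(nAtomHeavy = sum(heavy),
    nC = sum(sym == "C"), nN = sum(sym == "N"), nO = sum(sym == "O"),
    nS = sum(sym == "S"), nP = sum(sym == "P"), nHalogen = sum(hal),
    nHetero = sum(het),
    nHTotal = sum(sym == "H") + sum(g$nh),
    nBonds = length(ord),
    nBondsSingle = sum(ord == 1L), nBondsDouble = sum(ord == 2L),
    nBondsTriple = sum(ord == 3L),
    maxDegree = if (length(deg)) max(deg) else 0,
    nBranchAtoms = sum(deg >= 3L),
    meanDegree = if (length(deg)) mean(deg) else 0,
    heteroFraction = if (sum(heavy) > 0) sum(het) / sum(heavy) else NA_real_)
}

#' Compute 2D molecular descriptors for a compound set
#'
#' Computes constitutional, topological and physicochemical descriptors per
#' compound: OpenBabel properties (molecular weight, logP, topological polar
#' surface area, molar refractivity, H-bond donor/acceptor counts), ring and
#' aromatic-ring counts, functional-group counts, and graph-derived atom,
#' bond and branching statistics. Descriptors that fail to compute for a
#' molecule are set to `NA` — never silently zero. A compound whose every
#' descriptor fails is excluded with a warning.
#'
#' 3D descriptors are not provided: they require conformer embedding, and no
#' deterministic conformer generator is available to this toolkit, so
#' `include_3d = TRUE` raises an error rather than producing irreproducible
#' values.
#'
#' @param records Compound dataset (see [read_dataset()]) or character
#'   vector of SMILES.
#' @param include_3d Must be `FALSE`; see Details.
#' @return Numeric matrix, compounds x descriptors; rownames are compound
#'   ids, colnames descriptor names.
#' @export
compute_descriptors <- function(records, include_3d = FALSE) {
  if (isTRUE(include_3d))
    bbb_error("bbbqsar_unsupported_error",
              paste("3D descriptors require deterministic conformer",
                    "generation, which is not available; use the 2D set"))
  if (is.character(records))
    records <- .as_dataset(sprintf("cmpd_%04d", seq_along(records)),
                           records, canonicalize_smiles(records),
                           rep(NA_real_, length(records)))
  smiles <- records$smiles_canonical
  p <- .parse_smiles(smiles)
  if (!all(p$valid))
    bbb_error("bbbqsar_parse_error",
              sprintf("unparseable SMILES in descriptor computation: %s",
                      paste(smiles[!p$valid], collapse = ", ")))
  sdfset <- p$sdf
  n <- length(ChemmineR::cid(sdfset))
  graphs <- .molgraphs(smiles)

  prop <- tryCatch(ChemmineR::propOB(sdfset), error = function(e) NULL)
  prop_cols <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  propm <- matrix(NA_real_, n, length(prop_cols),
                  dimnames = list(NULL, prop_cols))
  if (!is.null(prop) && nrow(prop) == n) {
    for (cn in intersect(prop_cols, names(prop)))
      propm[, cn] <- suppressWarnings(as.numeric(prop[[cn]]))
  } else {
    # one degenerate molecule (e.g. a single-atom structure) aborts the
    # whole OpenBabel batch; retry per molecule so only it gets NAs
    for (i in seq_len(n)) {
      pi <- tryCatch(ChemmineR::propOB(sdfset[i]), error = function(e) NULL)
      if (!is.null(pi) && nrow(pi) == 1L)
        for (cn in intersect(prop_cols, names(pi)))
          propm[i, cn] <- suppressWarnings(as.numeric(pi[[cn]]))
    }
  }
  # molecular weight from the graph (atomic masses + implicit hydrogens by
  # default valence) where the property layer failed
  na_mw <- which(!is.finite(propm[, "MW"]))
  for (i in na_mw)
    if (!is.null(graphs[[i]]))
      propm[i, "MW"] <- tryCatch(.graph_mw(graphs[[i]]),
                                 error = function(e) NA_real_)

  # ring perception fails on bond-less molecules, so count per molecule
  ringm <- t(vapply(seq_len(n), function(i) {
    sdf <- sdfset[[i]]
    bb <- ChemmineR::bondblock(sdf)
    n_bonds <- if (is.null(bb) || length(dim(bb)) != 2L) 0L else nrow(bb)
    if (n_bonds < 3L) return(c(ringCount = 0, aromRingCount = 0))
    tryCatch({
      r <- ChemmineR::rings(sdf, type = "count", upper = 12, arom = TRUE)
      c(ringCount = as.numeric(r[["RINGS"]]),
        aromRingCount = as.numeric(r[["AROMATIC"]]))
    }, error = function(e) c(ringCount = NA_real_, aromRingCount = NA_real_))
  }, numeric(2)))

  grpm <- tryCatch({
    g <- ChemmineR::groups(sdfset, type = "countMA")
    if (is.null(dim(g))) g <- matrix(g, nrow = 1, dimnames = list(NULL, names(g)))
    storage.mode(g) <- "double"
    colnames(g) <- paste0("grp", colnames(g))
    g
  }, error = function(e) NULL)

  graph_na <- rep(NA_real_, 17)
  names(graph_na) <- c("nAtomHeavy", "nC", "nN", "nO", "nS", "nP", "nHalogen",
                       "nHetero", "nHTotal", "nBonds", "nBondsSingle",
                       "nBondsDouble", "nBondsTriple", "maxDegree",
                       "nBranchAtoms", "meanDegree", "heteroFraction")
  graphm <- t(vapply(seq_len(n), function(i) {
    if (is.null(graphs[[i]])) return(graph_na)
    tryCatch(.graph_descriptors(graphs[[i]]), error = function(e) graph_na)
  }, numeric(17)))

  out <- cbind(propm, ringm, graphm)
  if (!is.null(grpm) && nrow(grpm) == n) out <- cbind(out, grpm)
  # derived composites
  out <- cbind(out,
               MWperHeavy = out[, "MW"] / pmax(out[, "nAtomHeavy"], 1),
               bondPerAtom = out[, "nBonds"] / pmax(out[, "nAtomHeavy"], 1))
  rownames(out) <- records$id
  all_na <- apply(out, 1L, function(r) all(!is.finite(r)))
  if (any(all_na)) {
    warning(sprintf("%d compound(s) excluded: every descriptor failed (%s)",
                    sum(all_na), paste(records$id[all_na], collapse = ", ")))
    out <- out[!all_na, , drop = FALSE]
  }
  out
}

#' Remove descriptor columns with missing or non-finite entries
#'
#' Any column containing at least one missing (`NA`/`NaN`) or infinite value
#' across the dataset is removed; compound rows are unchanged. Non-finite
#' values are treated as missing because they are equally unusable for
#' model fitting. Idempotent.
#'
#' @param table Numeric descriptor matrix (compounds x descriptors).
#' @return The matrix restricted to fully finite columns.
#' @export
prune_missing <- function(table) {
  stopifnot(is.matrix(table))
  ok <- apply(table, 2L, function(col) all(is.finite(col)))
  if (!any(ok))
    bbb_error("bbbqsar_empty_error",
              "all descriptor columns contain missing values; dataset unusable")
  table[, ok, drop = FALSE]
}

#' Fit a standard scaler on training descriptors
#'
#' Records per-descriptor mean and sample standard deviation (n-1 denominator)
#' from the training rows. Zero-variance columns are dropped with a warning
#' before scaling, so every retained descriptor has sd > 0.
#'
#' @param table Numeric descriptor matrix of training rows (pruned, finite).
#' @return Object of class `bbb_scaler`: list with `names`, `mean`, `sd`.
#' @export
fit_scaler <- function(table) {
  stopifnot(is.matrix(table), nrow(table) >= 2L)
  mu <- colMeans(table)
  sd_ <- apply(table, 2L, stats::sd)
  keep <- is.finite(sd_) & sd_ > 0
  if (!all(keep))
    warning(sprintf("%d zero-variance column(s) dropped before scaling: %s",
                    sum(!keep),
                    paste(colnames(table)[!keep], collapse = ", ")))
  if (!any(keep))
    bbb_error("bbbqsar_empty_error", "no non-constant descriptor columns")
  structure(list(names = colnames(table)[keep], mean = mu[keep], sd = sd_[keep]),
            class = "bbb_scaler")
}

#' Apply (or invert) a fitted standard scaler
#'
#' Transforms each retained column j as `(x - mean_j) / sd_j` using the
#' training statistics stored in the scaler — held-out rows are transformed
#' with training-set statistics, never their own. `inverse = TRUE` undoes
#' the transformation exactly.
#'
#' @param table Numeric matrix whose columns cover the scaler's names.
#' @param params A `bbb_scaler` from [fit_scaler()].
#' @param inverse Invert instead of apply.
#' @return Scaled numeric matrix restricted to the scaler's columns, in the
#'   scaler's column order.
#' @export
apply_scaler <- function(table, params, inverse = FALSE) {
  stopifnot(inherits(params, "bbb_scaler"), is.matrix(table))
  missing_cols <- setdiff(params$names, colnames(table))
  if (length(missing_cols) > 0L)
    bbb_error("bbbqsar_schema_error",
              sprintf("columns missing for scaling: %s",
                      paste(missing_cols, collapse = ", ")))
  x <- table[, params$names, drop = FALSE]
  if (inverse)
    sweep(sweep(x, 2L, params$sd, `*`), 2L, params$mean, `+`)
  else
    sweep(sweep(x, 2L, params$mean, `-`), 2L, params$sd, `/`)
}
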