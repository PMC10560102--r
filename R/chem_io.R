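# Compound dataset I/O and SMILES validation/canonicalization.
#
# A compound dataset is a plain data.frame with columns
#   id, smiles_raw, smiles_canonical, logbb
# (logbb may be NA throughout for query sets). Rows rejected at parse time
# are recorded in attr(x, "rejected") as a data.frame (row, smiles, reason).

# Surface-syntax SMILES check. OpenBabel silently "repairs" some malformed
# strings (e.g. an unclosed branch), so structural parsing alone cannot
# reject them; this catches unbalanced branches/brackets and dangling ring
# closures before the structure round-trip.
.smiles_syntax_ok <- function(s) {
  s <- trimws(s)
  if (is.na(s) || !nzchar(s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
  if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
  depth <- 0
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1
    if (ch == ")") { depth <- depth - 1; if (depth < 0) return(FALSE) }
  }
  # ring-closure digits must pair up (ignore digits inside [] and after %)
  bare <- gsub("\\[[^]]*\\]", "", s)
  bare <- gsub("%[0-9]{2}", "", bare)
  digits <- regmatches(bare, gregexpr("[0-9]", bare))[[1]]
  if (length(digits) > 0L && any(table(digits) %% 2 != 0)) return(FALSE)
  TRUE
}

# Molecular graphs parsed from OpenBabel's V2000 molfile output: per
# molecule a list with atom symbols, formal charges, implicit hydrogen
# counts, and bond triples (a1, a2, order). Fingerprinting and the
# graph-derived descriptors consume these directly.
.molgraphs <- function(smiles) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF",
                              paste0(paste(trimws(smiles), collapse = "\n"),
                                     "\n")),
    error = function(e) "")
  recs <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  out <- vector("list", length(smiles))
  if (length(recs) != length(smiles)) return(out)  # all invalid
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  for (k in seq_along(recs)) {
    lines <- strsplit(recs[k], "\n", fixed = TRUE)[[1]]
    if (length(lines) < 4L) next
    counts <- lines[4L]
    natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
    nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
    if (is.na(natoms) || natoms < 1L || is.na(nbonds)) next
    atom_lines <- lines[4L + seq_len(natoms)]
    sym <- trimws(substr(atom_lines, 32L, 34L))
    charge <- integer(natoms)
    a1 <- a2 <- ord <- integer(0)
    if (nbonds > 0L) {
      bond_lines <- lines[4L + natoms + seq_len(nbonds)]
      a1 <- as.integer(substr(bond_lines, 1L, 3L))
      a2 <- as.integer(substr(bond_lines, 4L, 6L))
      ord <- as.integer(substr(bond_lines, 7L, 9L))
    }
    for (ln in grep("^M  CHG", lines, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
      npairs <- f[1L]
      for (p in seq_len(npairs))
        charge[f[2L * p]] <- f[2L * p + 1L]
    }
    valsum <- numeric(natoms)
    for (i in seq_along(a1)) {
      valsum[a1[i]] <- valsum[a1[i]] + ord[i]
      valsum[a2[i]] <- valsum[a2[i]] + ord[i]
    }
    defval <- .DEFAULT_VALENCE[sym]
    eff <- ifelse(sym %in% c("N", "P"), defval + charge, defval - abs(charge))
    nh <- pmax(0, ifelse(is.na(eff), 0, eff) - valsum)
    out[[k]] <- list(sym = sym, charge = charge, nh = nh, valsum = valsum,
                     a1 = a1, a2 = a2, ord = ord, natoms = natoms)
  }
  out
}

# Parse SMILES through OpenBabel and flag invalid entries: a SMILES is valid
# iff it passes the syntax check and OpenBabel yields at least one atom.
.parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  valid <- vapply(smiles, .smiles_syntax_ok, logical(1), USE.NAMES = FALSE)
  sdf <- NULL
  if (any(valid)) {
    nm <- paste0("m", seq_len(n))[valid]
    sm <- trimws(smiles[valid])
    names(sm) <- nm
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(sm)),
      error = function(e) NULL
    )
    if (is.null(sdf)) {
      valid[] <- FALSE
    } else {
      natoms <- vapply(seq_along(ChemmineR::cid(sdf)), function(i) {
        nrow(ChemmineR::atomblock(sdf[[i]]))
      }, integer(1))
      ok <- natoms > 0L
      valid[valid] <- ok
      sdf <- if (any(ok)) sdf[ok] else NULL
    }
  }
  list(sdf = sdf, valid = valid)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form so that any two notations of
#' the same molecule map to one string. Canonicalization is idempotent.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "CCO"))  # identical outputs
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) == 0L || any(!nzchar(trimws(smiles))))
    bbb_error("bbbqsar_parse_error", "SMILES input must be non-empty strings")
  p <- .parse_smiles(smiles)
  if (!all(p$valid))
    bbb_error("bbbqsar_parse_error",
              sprintf("unparseable SMILES: %s",
                      paste(smiles[!p$valid], collapse = ", ")),
              smiles = smiles[!p$valid])
  out <- ChemmineOB::convertFormat("SMI", "CAN",
                                   paste0(paste(trimws(smiles), collapse = "\n"), "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  can <- vapply(strsplit(lines, "[ \t]"), `[`, character(1), 1L)
  if (length(can) != length(smiles))
    bbb_error("bbbqsar_parse_error", "canonicalization dropped entries unexpectedly")
  can
}

.as_dataset <- function(id, smiles_raw, smiles_canonical, logbb) {
  data.frame(id = as.character(id),
             smiles_raw = as.character(smiles_raw),
             smiles_canonical = as.character(smiles_canonical),
             logbb = as.numeric(logbb),
             stringsAsFactors = FALSE)
}

#' Read a compound dataset from CSV or SMI
#'
#' Reads one compound per row, validates and canonicalizes SMILES, and drops
#' rows whose SMILES fail to parse (recorded in `attr(,"rejected")` with row
#' numbers and a warning, so large screening runs proceed). Duplicate
#' canonical SMILES keep the first occurrence with a warning.
#'
#' @param path Path to the input file.
#' @param format `"csv"` (header required) or `"smi"` (one SMILES per line,
#'   optional whitespace-separated id).
#' @param smiles_col,logbb_col,id_col CSV column names; `logbb_col` and
#'   `id_col` are optional in the file.
#' @return data.frame with columns `id`, `smiles_raw`, `smiles_canonical`,
#'   `logbb` (NA when absent); attributes `rejected` and `duplicates`.
#' @export
read_dataset <- function(path, format = c("csv", "smi"),
                         smiles_col = "smiles", logbb_col = "logbb",
                         id_col = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    bbb_error("bbbqsar_io_error", sprintf("input file not found: %s", path))
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!smiles_col %in% names(raw))
      bbb_error("bbbqsar_schema_error",
                sprintf("missing SMILES column '%s' (found: %s)",
                        smiles_col, paste(names(raw), collapse = ", ")))
    smiles <- as.character(raw[[smiles_col]])
    logbb <- if (logbb_col %in% names(raw)) as.numeric(raw[[logbb_col]]) else
      rep(NA_real_, nrow(raw))
    ids <- if (!is.null(id_col) && id_col %in% names(raw))
      as.character(raw[[id_col]]) else sprintf("cmpd_%04d", seq_along(smiles))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    tok <- strsplit(trimws(lines), "[ \t]+")
    smiles <- vapply(tok, `[`, character(1), 1L)
    ids <- vapply(seq_along(tok), function(i)
      if (length(tok[[i]]) > 1L) tok[[i]][2L] else sprintf("cmpd_%04d", i),
      character(1))
    logbb <- rep(NA_real_, length(smiles))
  }
  nonempty <- !is.na(smiles) & nzchar(trimws(smiles))
  smiles <- smiles[nonempty]; logbb <- logbb[nonempty]; ids <- ids[nonempty]
  rows <- which(nonempty)
  if (length(smiles) == 0L)
    bbb_error("bbbqsar_empty_error", "no compound rows in input")

  p <- .parse_smiles(smiles)
  rejected <- data.frame(row = rows[!p$valid], smiles = smiles[!p$valid],
                         reason = rep("SMILES failed to parse", sum(!p$valid)),
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L)
    warning(sprintf("%d row(s) with unparseable SMILES skipped (rows: %s)",
                    nrow(rejected), paste(rejected$row, collapse = ", ")))
  keep <- p$valid
  if (!any(keep))
    bbb_error("bbbqsar_empty_error", "no valid compounds after SMILES parsing")
  smiles <- smiles[keep]; logbb <- logbb[keep]; ids <- ids[keep]

  can <- canonicalize_smiles(smiles)
  dup <- duplicated(can)
  duplicates <- data.frame(id = ids[dup], smiles = smiles[dup],
                           canonical = can[dup], stringsAsFactors = FALSE)
  if (any(dup))
    warning(sprintf("%d duplicate canonical SMILES dropped (kept first occurrence)",
                    sum(dup)))
  out <- .as_dataset(ids[!dup], smiles[!dup], can[!dup], logbb[!dup])
  attr(out, "rejected") <- rejected
  attr(out, "duplicates") <- duplicates
  out
}

#' Write logBB predictions for a set of compounds
#'
#' Writes a CSV with columns `id`, `smiles`, `predicted_logbb`, `bbb_class`.
#' When `labels` is omitted the class is derived from the predictions with
#' [binarize_logbb()] at the given cutoff.
#'
#' @param records Compound dataset (see [read_dataset()]).
#' @param predictions Numeric vector of predicted logBB, one per record.
#' @param path Output file path.
#' @param labels Optional character vector `"permeable"`/`"nonpermeable"`.
#' @param cutoff logBB classification cutoff used when `labels` is NULL.
#' @param digits Printed precision for predicted values.
#' @return The path, invisibly.
#' @export
write_predictions <- function(records, predictions, path, labels = NULL,
                              cutoff = -1.0, digits = 6) {
  n <- nrow(records)
  if (length(predictions) != n)
    bbb_error("bbbqsar_schema_error",
              sprintf("length mismatch: %d records vs %d predictions",
                      n, length(predictions)))
  if (is.null(labels)) {
    labels <- if (n > 0L) binarize_logbb(predictions, cutoff) else character(0)
  } else if (length(labels) != n) {
    bbb_error("bbbqsar_schema_error",
              sprintf("length mismatch: %d records vs %d labels", n, length(labels)))
  }
  out <- data.frame(id = records$id,
                    smiles = records$smiles_canonical,
                    predicted_logbb = round(as.numeric(predictions), digits),
                    bbb_class = as.character(labels),
                    stringsAsFactors = FALSE)
  ok <- tryCatch({ utils::write.csv(out, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) bbb_error("bbbqsar_io_error", sprintf("cannot write to: %s", path))
  invisible(path)
}
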