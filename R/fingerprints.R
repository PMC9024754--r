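# Binary molecular fingerprints and Tanimoto similarity.
#
# All fingerprints are generated by OpenBabel (via ChemmineOB) and returned
# as 0/1 integer matrices (records x bits). Hashed classes (circular and
# path-based) are folded from OpenBabel's native length down to the
# configured width by OR-ing equal-sized blocks; keyed classes (SMARTS
# catalogs) keep their fixed catalog width.

.HASHED_CLASSES <- c("ecfp2", "ecfp4", "layered", "path_fp2")
.KEYED_WIDTH <- c(maccs = 168L, pubchem_like = 312L)  # catalog sizes, byte-padded

#' Fingerprint configuration
#'
#' Supported classes: `ecfp2` / `ecfp4` (circular, diameter 2 and 4, i.e.
#' radius 1 and 2), `path_fp2` (hashed linear paths), `layered` (two-layer
#' fingerprint: a hashed path layer and a circular layer, each `n_bits/2`
#' wide), `maccs` (MACCS key catalog) and `pubchem_like` (a fixed
#' substructure-key catalog of functional-group SMARTS patterns).
#'
#' @param fp_class Fingerprint class.
#' @param n_bits Bit-vector length; hashed classes accept 512, 1024, 2048 or
#'   4096. Keyed classes have a fixed catalog width and ignore this argument.
#' @return A `fingerprint_config`.
#' @export
fingerprint_config <- function(fp_class = c("ecfp4", "ecfp2", "layered",
                                            "path_fp2", "maccs",
                                            "pubchem_like"),
                               n_bits = 1024L) {
  fp_class <- match.arg(fp_class)
  if (fp_class %in% .HASHED_CLASSES) {
    if (!n_bits %in% c(512L, 1024L, 2048L, 4096L))
      stop("hashed fingerprint classes require n_bits in {512, 1024, 2048, 4096}")
  } else {
    n_bits <- .KEYED_WIDTH[[fp_class]]
  }
  structure(list(fp_class = fp_class, n_bits = as.integer(n_bits),
                 generator_id = "openbabel"),
            class = "fingerprint_config")
}

#' @export
print.fingerprint_config <- function(x, ...) {
  cat(sprintf("Fingerprint config: %s, %d bits (%s)\n",
              x$fp_class, x$n_bits, x$generator_id))
  invisible(x)
}

# OR-fold a raw fingerprint matrix down to n_bits columns.
fold_bits <- function(m, n_bits) {
  if (ncol(m) == n_bits) return(m)
  if (ncol(m) %% n_bits != 0L)
    stop("cannot fold ", ncol(m), " bits into ", n_bits)
  k <- ncol(m) / n_bits
  out <- m[, seq_len(n_bits), drop = FALSE]
  for (i in seq_len(k - 1)) {
    out <- out | m[, i * n_bits + seq_len(n_bits), drop = FALSE]
  }
  storage.mode(out) <- "integer"
  out
}

# FPS hex -> 0/1 bits in OpenBabel's in-memory bit order (FPS stores each
# byte most-significant-bit first; the in-memory order is the reverse
# within each byte).
fps_hex_to_bits <- function(hex) {
  nib <- strtoi(strsplit(hex, "", fixed = TRUE)[[1]], 16L)
  hi <- nib[seq(1, length(nib), 2)]
  lo <- nib[seq(2, length(nib), 2)]
  bytes <- rbind(bitwAnd(lo, 1L), bitwAnd(lo, 2L), bitwAnd(lo, 4L),
                 bitwAnd(lo, 8L), bitwAnd(hi, 1L), bitwAnd(hi, 2L),
                 bitwAnd(hi, 4L), bitwAnd(hi, 8L))
  as.integer(bytes > 0L)
}

# Raw OpenBabel fingerprints through the obabel executable's FPS output.
# The short-lived subprocess keeps per-molecule allocations of the
# fingerprint plugins out of the R session, which matters for
# library-sized batches.
ob_fingerprints <- function(smiles, name) {
  smi_file <- tempfile(fileext = ".smi")
  fps_file <- tempfile(fileext = ".fps")
  on.exit(unlink(c(smi_file, fps_file)), add = TRUE)
  writeLines(sprintf("%s m%08d", smiles, seq_along(smiles)), smi_file)
  status <- suppressWarnings(system2(
    "obabel", c(shQuote(smi_file), "-ofps", paste0("-xf", name),
                "-O", shQuote(fps_file)),
    stdout = FALSE, stderr = FALSE))
  body <- if (file.exists(fps_file)) {
    lines <- readLines(fps_file)
    lines[!startsWith(lines, "#")]
  } else character(0)
  if (status != 0 || length(body) != length(smiles))
    stop("fingerprint generation failed for ",
         length(smiles) - length(body), " of ", length(smiles),
         " structure(s); check SMILES validity")
  titles <- sub("^.*\t", "", body)
  hex <- sub("\t.*$", "", body)
  hex <- hex[match(sprintf("m%08d", seq_along(smiles)), titles)]
  if (anyNA(hex)) stop("fingerprint output does not cover every structure")
  t(vapply(hex, fps_hex_to_bits, integer(nchar(hex[1]) * 4L),
           USE.NAMES = FALSE))
}

#' Compute fingerprints for a set of structures
#'
#' @param smiles Character vector of SMILES.
#' @param config A [fingerprint_config()].
#' @return Integer 0/1 matrix (length(smiles) x n_bits) with the
#'   configuration attached as attribute `config` and `smiles` names as row
#'   names when available.
#' @export
compute_fingerprints <- function(smiles, config = fingerprint_config()) {
  stopifnot(inherits(config, "fingerprint_config"))
  m <- switch(config$fp_class,
    ecfp2 = fold_bits(ob_fingerprints(smiles, "ECFP2"), config$n_bits),
    ecfp4 = fold_bits(ob_fingerprints(smiles, "ECFP4"), config$n_bits),
    path_fp2 = fold_bits(ob_fingerprints(smiles, "FP2"), config$n_bits),
    layered = cbind(
      fold_bits(ob_fingerprints(smiles, "FP2"), config$n_bits / 2L),
      fold_bits(ob_fingerprints(smiles, "ECFP2"), config$n_bits / 2L)),
    maccs = ob_fingerprints(smiles, "MACCS"),
    pubchem_like = ob_fingerprints(smiles, "FP4"))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(names(smiles), NULL)
  attr(m, "config") <- config
  m
}

#' Compute a single fingerprint
#'
#' @inheritParams compute_fingerprints
#' @return Integer 0/1 vector of length `config$n_bits` with attribute
#'   `config`.
#' @export
compute_fingerprint <- function(smiles, config = fingerprint_config()) {
  stopifnot(length(smiles) == 1L)
  m <- compute_fingerprints(smiles, config)
  structure(as.integer(m[1L, ]), config = attr(m, "config"))
}

check_fp_configs <- function(a, b) {
  ca <- attr(a, "config"); cb <- attr(b, "config")
  if (!is.null(ca) && !is.null(cb) && !identical(unclass(ca), unclass(cb)))
    stop("fingerprint configurations do not match")
  la <- if (is.matrix(a)) ncol(a) else length(a)
  lb <- if (is.matrix(b)) ncol(b) else length(b)
  if (la != lb) stop("fingerprint lengths differ: ", la, " vs ", lb)
}

#' Tanimoto similarity of two bit fingerprints
#'
#' `|a AND b| / |a OR b|`; defined as 1 when both vectors are all-zero
#' (identical absence of features) and 0 when exactly one is all-zero.
#'
#' @param a,b 0/1 vectors of equal length (configs must match if attached).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  check_fp_configs(a, b)
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0L) return(1)
  sum(a & b) / un
}

#' Pairwise Tanimoto similarity between two fingerprint matrices
#'
#' @param a,b 0/1 matrices with matching bit width (rows are molecules).
#' @return `nrow(a)` x `nrow(b)` similarity matrix.
#' @export
tanimoto_matrix <- function(a, b) {
  check_fp_configs(a, b)
  a <- as.matrix(a); b <- as.matrix(b)
  inter <- a %*% t(b)
  un <- outer(rowSums(a), rowSums(b), "+") - inter
  s <- inter / un
  s[un == 0] <- 1
  s
}

#' Maximum similarity of a fingerprint to a pool
#'
#' @param fp A single 0/1 fingerprint vector.
#' @param pool Fingerprint matrix (rows are pool members), non-empty.
#' @return List with `score` (maximum Tanimoto) and `index` (first argmax).
#' @export
max_similarity_to_set <- function(fp, pool) {
  if (is.null(dim(pool)) || nrow(pool) == 0L) stop("empty fingerprint pool")
  s <- as.numeric(tanimoto_matrix(matrix(as.integer(fp), nrow = 1), pool))
  list(score = max(s), index = which.max(s))
}

#' Fingerprints as compact hex strings
#'
#' @param fps Fingerprint matrix from [compute_fingerprints()].
#' @return Character vector, one hex string per row.
#' @export
fingerprint_hex <- function(fps) {
  apply(fps, 1, function(bits) {
    pad <- (4 - length(bits) %% 4) %% 4
    bits <- c(bits, rep(0L, pad))
    nib <- matrix(bits, nrow = 4)
    paste(sprintf("%x", 8 * nib[1, ] + 4 * nib[2, ] + 2 * nib[3, ] + nib[4, ]),
          collapse = "")
  })
}

#' Export a fingerprint matrix as CSV
#'
#' Writes a records-by-bits 0/1 table with `record_id` as the first column.
#'
#' @param fps Fingerprint matrix.
#' @param record_ids Record identifiers, one per row.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_fingerprints <- function(fps, record_ids, path) {
  stopifnot(length(record_ids) == nrow(fps))
  df <- data.frame(record_id = record_ids, as.data.frame(unclass(fps)[, ]),
                   check.names = FALSE)
  names(df) <- c("record_id", sprintf("bit%04d", seq_len(ncol(fps))))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
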