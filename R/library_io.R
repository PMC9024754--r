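# Derivative-library input, validation and output.
#
# A derivative library is a data frame with one row per TMS derivative:
#   record_id, base_id, name, smiles, n_tms, ri, monoisotopic_mass
# `base_id` groups the TMS variants of the same underlying metabolite.
# Validation mirrors curation of real libraries: records lacking a parseable
# structure or a reference RI are discarded (and reported), and a stored TMS
# count that contradicts the structure is treated as a curation error.

.LIBRARY_COLUMNS <- c("record_id", "base_id", "name", "smiles", "n_tms", "ri")

#' Construct a validated derivative library
#'
#' @param records Data frame with columns `record_id`, `base_id`, `name`,
#'   `smiles`, `n_tms`, `ri` (and optionally `monoisotopic_mass`).
#' @param provenance Free-text description of where the records came from.
#' @param discards Optional data frame (`record_id`, `reason`) of records
#'   dropped during validation, kept as an attribute for reporting.
#' @return A `derivative_library` (a data frame subclass).
#' @export
derivative_library <- function(records, provenance = "", discards = NULL) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.LIBRARY_COLUMNS, names(records))
  if (length(missing_cols))
    stop("library is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L)
    stop("empty library: no valid records")
  if (anyDuplicated(records$record_id))
    stop("duplicate record_id(s): ",
         paste(unique(records$record_id[duplicated(records$record_id)]),
               collapse = ", "))
  if (any(!is.finite(records$ri) | records$ri <= 0))
    stop("all reference RI values must be finite and > 0")
  rownames(records) <- NULL
  structure(records,
            provenance = provenance,
            discards = discards %||%
              data.frame(record_id = character(0), reason = character(0)),
            class = c("derivative_library", "data.frame"))
}

#' @export
print.derivative_library <- function(x, ...) {
  d <- attr(x, "discards")
  cat(sprintf("Derivative library: %d records, %d base metabolites\n",
              nrow(x), length(unique(x$base_id))))
  cat(sprintf("TMS counts: %s\n",
              paste(sprintf("%d:%d", as.integer(names(table(x$n_tms))),
                            as.integer(table(x$n_tms))), collapse = " ")))
  if (nzchar(attr(x, "provenance") %||% ""))
    cat("Provenance:", attr(x, "provenance"), "\n")
  cat(sprintf("Discarded during validation: %d\n", nrow(d)))
  invisible(x)
}

# Validate raw records; returns a derivative_library with a discard report.
validate_records <- function(raw, provenance = "") {
  for (col in c("record_id", "base_id", "name", "smiles"))
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  raw$record_id <- as.character(raw$record_id)
  raw$record_id[is.na(raw$record_id) | !nzchar(raw$record_id)] <-
    sprintf("row%d", which(is.na(raw$record_id) | !nzchar(raw$record_id)))
  reasons <- rep(NA_character_, nrow(raw))

  no_smiles <- is.na(raw$smiles) | !nzchar(trimws(as.character(raw$smiles)))
  reasons[no_smiles] <- "missing SMILES"
  ri <- suppressWarnings(as.numeric(raw$ri %||% NA))
  bad_ri <- is.na(ri) | ri <= 0
  reasons[is.na(reasons) & bad_ri] <- "missing or non-positive RI"

  ok <- is.na(reasons)
  if (any(ok)) {
    valid <- smiles_is_valid(as.character(raw$smiles[ok]))
    reasons[which(ok)[!valid]] <- "unparseable SMILES"
  }
  ok <- is.na(reasons)
  n_tms_obs <- rep(NA_integer_, nrow(raw))
  if (any(ok))
    n_tms_obs[ok] <- count_tms_groups(as.character(raw$smiles[ok]))
  if ("n_tms" %in% names(raw)) {
    stored <- suppressWarnings(as.integer(raw$n_tms))
    conflict <- ok & !is.na(stored) & stored != n_tms_obs
    reasons[conflict] <- sprintf(
      "stored n_tms (%d) conflicts with structure (%d)",
      stored[conflict], n_tms_obs[conflict])
  }
  ok <- is.na(reasons)
  if (!any(ok)) stop("empty library: no valid records")

  kept <- raw[ok, , drop = FALSE]
  kept$n_tms <- n_tms_obs[ok]
  kept$ri <- ri[ok]
  kept$name <- as.character(kept$name)
  kept$name[is.na(kept$name)] <- kept$record_id[is.na(kept$name)]
  kept$base_id <- as.character(kept$base_id)
  kept$base_id[is.na(kept$base_id)] <- kept$record_id[is.na(kept$base_id)]
  kept$smiles <- as.character(kept$smiles)
  if (!"monoisotopic_mass" %in% names(kept) ||
      any(is.na(kept$monoisotopic_mass)))
    kept$monoisotopic_mass <- monoisotopic_mass(kept$smiles)
  kept <- kept[, c(.LIBRARY_COLUMNS, "monoisotopic_mass")]

  discards <- data.frame(record_id = raw$record_id[!ok],
                         reason = reasons[!ok],
                         stringsAsFactors = FALSE)
  prov <- sprintf("%s | %d read, %d kept, %d discarded",
                  provenance, nrow(raw), nrow(kept), nrow(discards))
  derivative_library(kept, provenance = prov, discards = discards)
}

#' Read a derivative library from CSV, TSV or SDF
#'
#' Records failing validation (missing or unparseable SMILES, missing RI, a
#' stored TMS count contradicting the structure) are discarded; the discard
#' report is attached as the `discards` attribute and summarised in the
#' `provenance` attribute. TMS counts are always recomputed from the
#' structure and monoisotopic masses are derived from the molecular formula.
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"` or `"sdf"`. SDF files carry the identifiers
#'   and RI in the SD tags `<RECORD_ID>`, `<BASE_ID>`, `<NAME>`, `<RI>`.
#' @return A [derivative_library()].
#' @export
read_library <- function(path, format = c("csv", "tsv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read library file: ", path)
  if (format %in% c("csv", "tsv")) {
    raw <- utils::read.table(path, header = TRUE,
                             sep = if (format == "csv") "," else "\t",
                             quote = "\"", comment.char = "",
                             stringsAsFactors = FALSE, check.names = TRUE)
    if (nrow(raw) == 0L) stop("empty library: no valid records")
    needed <- setdiff(.LIBRARY_COLUMNS, c("n_tms", "name"))
    missing_cols <- setdiff(needed, names(raw))
    if (length(missing_cols))
      stop("library table is missing column(s): ",
           paste(missing_cols, collapse = ", "))
  } else {
    raw <- read_sdf_records(path)
    if (nrow(raw) == 0L) stop("empty library: no valid records")
  }
  validate_records(raw, provenance = paste0(format, ":", basename(path)))
}

# SDF -> raw record data frame (structure re-exported as SMILES).
read_sdf_records <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  n <- length(sdfs)
  if (n == 0L)
    return(data.frame(record_id = character(0), smiles = character(0)))
  tags <- lapply(seq_len(n), function(i) {
    db <- ChemmineR::datablock(sdfs[[i]])
    as.list(db)
  })
  get_tag <- function(i, key) {
    v <- tags[[i]][[key]]
    if (is.null(v)) NA_character_ else as.character(v)
  }
  smiles <- vapply(seq_len(n), function(i) {
    s <- try(suppressWarnings(as.character(
      ChemmineR::sdf2smiles(sdfs[i]))), silent = TRUE)
    if (inherits(s, "try-error") || !length(s)) NA_character_ else s[1]
  }, character(1))
  data.frame(
    record_id = vapply(seq_len(n), get_tag, character(1), key = "RECORD_ID"),
    base_id = vapply(seq_len(n), get_tag, character(1), key = "BASE_ID"),
    name = vapply(seq_len(n), get_tag, character(1), key = "NAME"),
    smiles = smiles,
    ri = suppressWarnings(as.numeric(
      vapply(seq_len(n), get_tag, character(1), key = "RI"))),
    stringsAsFactors = FALSE)
}

#' Write a derivative library to CSV or TSV
#'
#' @param library A [derivative_library()].
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(library, "derivative_library"))
  utils::write.table(as.data.frame(library), path,
                     sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- spectra ---------------------------------------------------------------

#' Construct a mass spectrum
#'
#' @param mz m/z values in Da (positive; sorted internally, exact duplicates
#'   are merged by summing their intensities).
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param normalized Flag recording whether intensities are normalised.
#' @return An `ms_spectrum`: list with `mz`, `intensity`, `normalized`.
#' @export
ms_spectrum <- function(mz, intensity, normalized = FALSE) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1L)
  if (any(!is.finite(mz) | mz <= 0)) stop("all m/z values must be > 0")
  if (any(!is.finite(intensity) | intensity < 0))
    stop("all intensities must be >= 0")
  if (!any(intensity > 0)) stop("spectrum has no peak with intensity > 0")
  o <- order(mz)
  mz <- unname(mz[o]); intensity <- unname(intensity[o])
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  }
  structure(list(mz = mz, intensity = intensity, normalized = normalized),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("Mass spectrum: %d peaks, m/z %.1f-%.1f, base peak %.1f\n",
              length(x$mz), min(x$mz), max(x$mz),
              x$mz[which.max(x$intensity)]))
  invisible(x)
}

#' Read spectra from an MSP file
#'
#' Minimal MSP dialect: each record starts with `Name:`, carries
#' `Num Peaks:` and is followed by whitespace- or semicolon-separated
#' m/z-intensity pairs. Unknown header keys are ignored.
#'
#' @param path MSP file path.
#' @return Named list of [ms_spectrum()] keyed by record name; an empty file
#'   yields an empty list.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("cannot read MSP file: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  name <- NULL; mz <- numeric(0); int <- numeric(0)
  flush <- function() {
    if (is.null(name)) return()
    if (name %in% names(out)) stop("duplicate spectrum id in MSP: ", name)
    out[[name]] <<- ms_spectrum(mz, int)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^Name:", ln, ignore.case = TRUE)) {
      flush()
      name <- trimws(sub("^Name:", "", ln, ignore.case = TRUE))
      mz <- numeric(0); int <- numeric(0)
    } else if (grepl("^[A-Za-z][A-Za-z0-9 _]*:", ln)) {
      next  # other header keys (Num Peaks, comments, ...) are ignored
    } else {
      toks <- strsplit(gsub(";", " ", ln), "[[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      vals <- suppressWarnings(as.numeric(toks))
      if (length(vals) == 0L || length(vals) %% 2 != 0L || anyNA(vals))
        stop("malformed peak line ", i, " in ", path, ": '", ln, "'")
      mz <- c(mz, vals[seq(1, length(vals), 2)])
      int <- c(int, vals[seq(2, length(vals), 2)])
    }
  }
  flush()
  out
}

#' Write spectra to an MSP file
#'
#' @param spectra Named list of [ms_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path) {
  stopifnot(is.list(spectra), !is.null(names(spectra)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(spectra)) {
    sp <- spectra[[id]]
    writeLines(c(sprintf("Name: %s", id),
                 sprintf("Num Peaks: %d", length(sp$mz)),
                 paste(sprintf("%.9g %.9g", sp$mz, sp$intensity),
                       collapse = "; "),
                 ""), con)
  }
  invisible(path)
}
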