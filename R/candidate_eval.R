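# Candidate ranking and filtering for CI/EI identification scenarios.
#
# An observed ion (CI: monoisotopic mass; EI: fragment spectrum) often
# matches several library entries. Each scenario draws seed metabolites,
# expands them with their potential interfering metabolites (PIMs) -- other
# records within a mass tolerance (CI) or above a spectral-similarity
# threshold (EI) -- trains on everything else, and asks how well the
# predicted-vs-reference RI error ranks the true identity and filters the
# impostors.

#' Cosine spectral similarity
#'
#' Bins m/z to unit bins, L2-normalises each binned intensity vector and
#' returns their cosine. Equals 1 for identical spectra and 0 for spectra
#' with no shared bins.
#'
#' @param a,b [ms_spectrum()] objects.
#' @return Similarity in `[0, 1]`.
#' @export
spectral_similarity <- function(a, b) {
  stopifnot(inherits(a, "ms_spectrum"), inherits(b, "ms_spectrum"))
  bin_vec <- function(sp) {
    bins <- round(sp$mz)
    v <- tapply(sp$intensity, bins, sum)
    if (all(v == 0)) stop("spectrum has all-zero intensities")
    v / sqrt(sum(v^2))
  }
  va <- bin_vec(a); vb <- bin_vec(b)
  shared <- intersect(names(va), names(vb))
  if (length(shared) == 0L) return(0)
  sum(va[shared] * vb[shared])
}

# All spectra as rows of one L2-normalised unit-bin intensity matrix, so a
# whole library's cosine similarities reduce to a matrix product.
spectra_matrix <- function(spectra) {
  binned <- lapply(spectra, function(sp) {
    v <- tapply(sp$intensity, round(sp$mz), sum)
    v / sqrt(sum(v^2))
  })
  bins <- sort(unique(unlist(lapply(binned, names))))
  m <- matrix(0, length(spectra), length(bins),
              dimnames = list(names(spectra), bins))
  for (i in seq_along(binned)) m[i, names(binned[[i]])] <- binned[[i]]
  m
}

#' Mass error in parts per million
#'
#' @param m_obs Observed mass, Da.
#' @param m_ref Reference mass, Da (> 0).
#' @return `1e6 * |m_obs - m_ref| / m_ref`.
#' @export
ppm_error <- function(m_obs, m_ref) {
  if (any(m_ref <= 0)) stop("reference mass must be > 0")
  1e6 * abs(m_obs - m_ref) / m_ref
}

#' Build seed + PIM candidate sets
#'
#' Draws `n_seeds` seed records uniformly without replacement. In CI mode a
#' seed's PIMs are all other records whose monoisotopic mass lies within
#' `ppm_tol` of the seed's; in EI mode, all records whose spectra reach
#' `sim_threshold` cosine similarity to the seed's spectrum. The training
#' set is every record not drawn into any candidate set; its fraction of
#' the library must reach `coverage_floor`.
#'
#' @param library A [derivative_library()] (with `monoisotopic_mass` for CI).
#' @param mode `"ci"` or `"ei"`.
#' @param n_seeds Number of seed metabolites (defaults mirror typical
#'   protocol sizes: 20 for CI, 70 for EI).
#' @param rng_seed Integer seed.
#' @param ppm_tol CI mass tolerance in ppm.
#' @param sim_threshold EI spectral-similarity threshold.
#' @param coverage_floor Minimum training-set fraction of the library.
#' @param spectra Named list of [ms_spectrum()] keyed by record id (EI only).
#' @return List of class `candidate_sets`: `sets` (each with `mode`,
#'   `seed_record_id`, `pim_ids`, `reference_ri`), `train_ids`, `coverage`.
#' @export
build_candidate_sets <- function(library, mode = c("ci", "ei"),
                                 n_seeds = NULL, rng_seed = 1L,
                                 ppm_tol = 10, sim_threshold = 0.8,
                                 coverage_floor = 0.8, spectra = NULL) {
  mode <- match.arg(mode)
  n_seeds <- n_seeds %||% if (mode == "ci") 20L else 70L
  n <- nrow(library)
  if (n_seeds >= n) stop("n_seeds must be smaller than the library")
  ids <- library$record_id
  if (mode == "ei") {
    if (is.null(spectra)) stop("EI mode requires spectra")
    missing_sp <- setdiff(ids, names(spectra))
    if (length(missing_sp))
      stop("missing spectra for ", length(missing_sp), " record(s), e.g. ",
           missing_sp[1])
  }
  seeds <- with_seed(derive_seed(rng_seed, "seeds"),
                     sort(sample.int(n, n_seeds)))
  spm <- if (mode == "ei") spectra_matrix(spectra[ids])
  sets <- lapply(seeds, function(i) {
    pims <- if (mode == "ci") {
      which(ppm_error(library$monoisotopic_mass,
                      library$monoisotopic_mass[i]) <= ppm_tol)
    } else {
      which(as.numeric(spm %*% spm[ids[i], ]) >= sim_threshold)
    }
    pims <- setdiff(pims, i)
    structure(list(mode = mode, seed_record_id = ids[i],
                   pim_ids = ids[pims], reference_ri = library$ri[i]),
              class = "candidate_set")
  })
  members <- unique(unlist(lapply(sets, function(s)
    c(s$seed_record_id, s$pim_ids))))
  train_ids <- setdiff(ids, members)
  coverage <- length(train_ids) / n
  if (coverage < coverage_floor)
    stop(sprintf(
      "training coverage %.2f below floor %.2f; use fewer seed metabolites",
      coverage, coverage_floor))
  structure(list(sets = sets, train_ids = train_ids, coverage = coverage,
                 mode = mode),
            class = "candidate_sets")
}

#' Rank the candidates of one set by predicted-RI error
#'
#' Candidates (the seed plus its PIMs) are scored by the relative error
#' between their predicted RI and the seed's reference RI (which stands in
#' for the experimental RI) and sorted ascending. The sort is stable --
#' ties keep input order, never favouring the true identity.
#'
#' @param set A `candidate_set`.
#' @param predicted_ri Named numeric vector of predicted RI covering all
#'   candidates.
#' @return Object of class `ranked_candidates`: data frame (`candidate_id`,
#'   `rel_error_pct`, `is_true`) ordered by error, with attributes
#'   `rank_of_true` and `n_candidates`.
#' @export
rank_candidates <- function(set, predicted_ri) {
  cand <- c(set$seed_record_id, set$pim_ids)
  miss <- setdiff(cand, names(predicted_ri))
  if (length(miss))
    stop("missing prediction for candidate(s): ",
         paste(miss, collapse = ", "))
  err <- 100 * abs(predicted_ri[cand] - set$reference_ri) / set$reference_ri
  # ties: the true identity loses, so exact prediction ties (e.g. identical
  # structures) never inflate its rank
  o <- order(err, cand == set$seed_record_id)
  out <- data.frame(candidate_id = cand[o], rel_error_pct = unname(err[o]),
                    is_true = cand[o] == set$seed_record_id,
                    stringsAsFactors = FALSE)
  structure(out, rank_of_true = which(out$is_true),
            n_candidates = length(cand),
            class = c("ranked_candidates", "data.frame"))
}

#' Rank distribution of the true identity by candidate-set size
#'
#' Summarises, for sets with 2, 3, and 4-or-more candidates, how often the
#' true identity ranks first, second, third or lower. Single-candidate sets
#' are excluded (their rank is trivially 1).
#'
#' @param ranked List of [rank_candidates()] results.
#' @return Data frame with one row per group (`C2`, `C3`, `C4plus`):
#'   `n_sets`, `rank1`, `rank2`, `rank3`, `beyond3`, `top3` (fractions).
#' @export
topk_summary <- function(ranked) {
  stopifnot(length(ranked) >= 1L)
  C <- vapply(ranked, attr, integer(1), "n_candidates")
  r <- vapply(ranked, attr, integer(1), "rank_of_true")
  grp <- ifelse(C == 2L, "C2", ifelse(C == 3L, "C3",
                ifelse(C >= 4L, "C4plus", NA)))
  keep <- !is.na(grp)
  grp <- factor(grp[keep], levels = c("C2", "C3", "C4plus"))
  r <- r[keep]
  rows <- lapply(levels(grp), function(g) {
    rg <- r[grp == g]
    if (length(rg) == 0L)
      return(data.frame(group = g, n_sets = 0L, rank1 = NA, rank2 = NA,
                        rank3 = NA, beyond3 = NA, top3 = NA))
    data.frame(group = g, n_sets = length(rg),
               rank1 = mean(rg == 1), rank2 = mean(rg == 2),
               rank3 = mean(rg == 3), beyond3 = mean(rg > 3),
               top3 = mean(rg <= 3))
  })
  do.call(rbind, rows)
}

#' Confusion counts at a filtering threshold
#'
#' A candidate is retained when its error is at or below the threshold.
#' Retained true identities are TP, filtered true identities FN, retained
#' PIMs FP and filtered PIMs TN.
#'
#' @param ranked List of [rank_candidates()] results.
#' @param threshold Filtering threshold in percent (>= 0).
#' @return List of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`,
#'   `threshold`.
#' @export
classify_at_threshold <- function(ranked, threshold) {
  stopifnot(threshold >= 0)
  tp <- fp <- tn <- fn <- 0L
  for (rc in ranked) {
    keep <- rc$rel_error_pct <= threshold
    tp <- tp + sum(keep & rc$is_true)
    fn <- fn + sum(!keep & rc$is_true)
    fp <- fp + sum(keep & !rc$is_true)
    tn <- tn + sum(!keep & !rc$is_true)
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Threshold %.1f %%: TP %d  FP %d  TN %d  FN %d\n",
              x$threshold, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' ROC curve over filtering thresholds
#'
#' Sweeps the filtering threshold from 0 to 100% in 1% steps; at each
#' threshold TPR = TP / (TP + FN) and FPR = FP / (FP + TN). AUC is the
#' trapezoid area over (FPR, TPR) after ordering by FPR.
#'
#' @param ranked List of [rank_candidates()] results containing at least one
#'   true and one false candidate overall.
#' @return Object of class `roc_curve`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_curve <- function(ranked) {
  n_true <- sum(vapply(ranked, function(rc) sum(rc$is_true), numeric(1)))
  n_false <- sum(vapply(ranked, function(rc) sum(!rc$is_true), numeric(1)))
  if (n_true == 0L) stop("no true candidates; TPR undefined")
  if (n_false == 0L) stop("no PIMs in any candidate set; FPR undefined")
  thresholds <- 0:100
  counts <- lapply(thresholds, function(t) classify_at_threshold(ranked, t))
  tpr <- vapply(counts, function(cc) cc$tp / (cc$tp + cc$fn), numeric(1))
  fpr <- vapply(counts, function(cc) cc$fp / (cc$fp + cc$tn), numeric(1))
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC over 0-100%% thresholds (step 1%%): AUC = %.3f\n", x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false positive rate", ylab = "true positive rate",
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
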