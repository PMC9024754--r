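# The TMS-counterpart linear baseline.
#
# The same metabolite observed with n and n+1 TMS groups elutes later by a
# roughly constant relative amount, so a simple linear regression of the
# higher-derivative RI on the lower-derivative RI predicts one from the
# other in either direction. This is the reference point against which the
# fingerprint models are judged.

#' Pair TMS counterparts of the same metabolite
#'
#' Finds base metabolites represented by exactly one record with `n_low` TMS
#' groups and exactly one with `n_low + 1`. Base ids with several records at
#' either level are skipped; the skip reasons are attached as attribute
#' `skipped`.
#'
#' @param library A [derivative_library()].
#' @param n_low Lower TMS count of the pair (1 and 2 are the well-populated
#'   levels in practice).
#' @return Data frame of class `tms_pairs` with `base_id`, `ri_low`,
#'   `ri_high`, `n_low`; possibly zero rows.
#' @export
pair_counterparts <- function(library, n_low = 1L) {
  stopifnot(n_low >= 0L)
  skipped <- character(0)
  rows <- lapply(split(seq_len(nrow(library)), library$base_id), function(ix) {
    lo <- ix[library$n_tms[ix] == n_low]
    hi <- ix[library$n_tms[ix] == n_low + 1L]
    if (length(lo) == 0L || length(hi) == 0L) return(NULL)
    if (length(lo) > 1L || length(hi) > 1L) {
      skipped <<- c(skipped, sprintf(
        "%s: ambiguous (%d records at %d TMS, %d at %d TMS)",
        library$base_id[ix[1]], length(lo), n_low, length(hi), n_low + 1L))
      return(NULL)
    }
    data.frame(base_id = library$base_id[lo], ri_low = library$ri[lo],
               ri_high = library$ri[hi], n_low = n_low,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(base_id = character(0), ri_low = numeric(0),
                      ri_high = numeric(0), n_low = integer(0))
  rownames(out) <- NULL
  structure(out, skipped = skipped, class = c("tms_pairs", "data.frame"))
}

#' Mean relative RI increase per added TMS group
#'
#' @param pairs A [pair_counterparts()] result with at least one pair.
#' @return Mean over pairs of `100 * (ri_high - ri_low) / ri_low` (percent);
#'   the median of the same per-pair ratios is attached as attribute
#'   `median_increase_pct`.
#' @export
mean_ri_increase <- function(pairs) {
  if (nrow(pairs) == 0L) stop("no TMS counterpart pairs")
  inc <- 100 * (pairs$ri_high - pairs$ri_low) / pairs$ri_low
  structure(mean(inc), median_increase_pct = median(inc))
}

#' Fit the TMS-counterpart shift model
#'
#' Ordinary least squares of `ri_high` on `ri_low`. Predictions are
#' available in both directions: forward through the fitted line and
#' backward through its algebraic inverse.
#'
#' @param pairs A [pair_counterparts()] result with at least two pairs and
#'   non-identical `ri_low` values.
#' @return Object of class `tms_shift` with `slope`, `intercept`, `n_low`,
#'   `n_pairs`.
#' @export
tms_shift <- function(pairs) {
  if (nrow(pairs) < 2L) stop("need at least 2 pairs to fit a shift model")
  if (diff(range(pairs$ri_low)) == 0)
    stop("degenerate pairs: all ri_low values are identical")
  fit <- lm(ri_high ~ ri_low, data = pairs)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n_low = pairs$n_low[1], n_pairs = nrow(pairs)),
            class = "tms_shift")
}

#' @rdname tms_shift
#' @export
fit_shift_model <- tms_shift

#' @export
print.tms_shift <- function(x, ...) {
  cat(sprintf(
    "TMS shift model (%d -> %d TMS): ri_high = %.4f * ri_low + %.2f  (n = %d)\n",
    x$n_low, x$n_low + 1L, x$slope, x$intercept, x$n_pairs))
  invisible(x)
}

#' @export
coef.tms_shift <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict RI across one TMS level
#'
#' @param object A [tms_shift()] model.
#' @param ri RI values of the known derivative.
#' @param direction `"forward"` predicts the (n+1)-TMS RI from the n-TMS RI;
#'   `"inverse"` applies the algebraic inverse of the fitted line.
#' @param ... Unused.
#' @return Predicted RI vector.
#' @export
predict.tms_shift <- function(object, ri, direction = c("forward", "inverse"),
                              ...) {
  direction <- match.arg(direction)
  if (direction == "forward") object$slope * ri + object$intercept
  else (ri - object$intercept) / object$slope
}

#' Holdout errors of a shift model
#'
#' @param model A [tms_shift()] model.
#' @param holdout_pairs Non-empty `tms_pairs` to evaluate on.
#' @return An [error_summary()] of predicted vs actual `ri_high`.
#' @export
shift_predict_errors <- function(model, holdout_pairs) {
  if (nrow(holdout_pairs) == 0L) stop("empty holdout set")
  pred <- predict(model, holdout_pairs$ri_low)
  error_summary(prediction_results(holdout_pairs$base_id, pred,
                                   holdout_pairs$ri_high))
}

#' Leave-one-out evaluation of the shift model
#'
#' Each pair is predicted by a model fitted on all remaining pairs.
#'
#' @param pairs At least three pairs.
#' @return An [error_summary()] of the leave-one-out predictions.
#' @export
loo_shift_errors <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 pairs for leave-one-out")
  pred <- vapply(seq_len(nrow(pairs)), function(i) {
    m <- tms_shift(pairs[-i, , drop = FALSE])
    predict(m, pairs$ri_low[i])
  }, numeric(1))
  error_summary(prediction_results(pairs$base_id, pred, pairs$ri_high))
}
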