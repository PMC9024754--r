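# Similarity-conditioned prediction-error calibration.
#
# Prediction error depends strongly on how similar a query structure is to
# the training set. Test-set errors are grouped by the query's maximum
# Tanimoto similarity to the training records into five ranges
# ([0.9,1], [0.8,0.9), [0.7,0.8), [0.6,0.7), [0,0.6)), and each range's
# empirical error distribution becomes a cumulative probability function
# (CPF): the estimated probability that a new prediction's relative error
# falls below a chosen threshold, given the query's similarity.

#' Default similarity ranges
#'
#' Five ranges partitioning `[0, 1]`, closed at the lower edge.
#'
#' @return Data frame with `label`, `lower`, `upper`, `lower_closed`,
#'   `upper_closed`.
#' @export
similarity_bins <- function() {
  data.frame(
    label = c("[0,0.6)", "[0.6,0.7)", "[0.7,0.8)", "[0.8,0.9)", "[0.9,1]"),
    lower = c(0, 0.6, 0.7, 0.8, 0.9),
    upper = c(0.6, 0.7, 0.8, 0.9, 1),
    lower_closed = TRUE,
    upper_closed = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Assign similarities to ranges
#'
#' Lower edges are closed, so 0.9 falls in the top range, 0.8 in the second
#' range from the top, and so on.
#'
#' @param similarity Numeric vector in `[0, 1]`.
#' @param bins Range definition as returned by [similarity_bins()].
#' @return Character vector of range labels (factor levels ordered from the
#'   lowest to the highest range).
#' @export
assign_bin <- function(similarity, bins = similarity_bins()) {
  if (any(!is.finite(similarity) | similarity < 0 | similarity > 1))
    stop("similarity values must lie in [0, 1]")
  idx <- findInterval(similarity, bins$lower)
  factor(bins$label[idx], levels = bins$label)
}

#' Equal-size random subsample across groups
#'
#' Downsamples every group without replacement to the size of the smallest
#' group, enabling statistically balanced comparisons between similarity
#' ranges.
#'
#' @param groups Named list of numeric vectors, all non-empty.
#' @param rng_seed Integer seed; the same seed reproduces the selection.
#' @return Named list of equal-length vectors.
#' @export
balanced_subsample <- function(groups, rng_seed = 1L) {
  empty <- names(groups)[vapply(groups, length, integer(1)) == 0L]
  if (length(empty))
    stop("empty group(s): ", paste(empty, collapse = ", "))
  m <- min(vapply(groups, length, integer(1)))
  out <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    keep <- with_seed(derive_seed(rng_seed, paste0("bal", i)),
                      sample.int(length(g), m))
    g[keep]
  })
  names(out) <- names(groups)
  out
}

#' Build the similarity-conditioned error CPF
#'
#' Routes each prediction's relative error to the similarity range of its
#' maximum training-set Tanimoto similarity and stores the sorted error
#' vector per range. The empirical CPF of a range is the right-continuous
#' step function of its sorted errors. All available errors are kept per
#' range (no balancing), maximising the resolution of the estimator;
#' balancing is only applied for between-range hypothesis tests.
#'
#' @param errors Relative prediction errors in percent.
#' @param similarities Maximum training-set similarity per error, in
#'   `[0, 1]`.
#' @param bins Range definition ([similarity_bins()]).
#' @return Object of class `error_cpf`; ranges that received no data are
#'   marked unqueryable.
#' @export
error_cpf <- function(errors, similarities, bins = similarity_bins()) {
  stopifnot(length(errors) == length(similarities))
  lab <- assign_bin(similarities, bins)
  per_bin <- lapply(split(errors, lab), sort)
  structure(list(bins = bins, errors = per_bin,
                 sizes = vapply(per_bin, length, integer(1))),
            class = "error_cpf")
}

#' @rdname error_cpf
#' @param results Protocol predictions carrying a `max_train_similarity`
#'   column (see [run_protocol()] with `with_similarity = TRUE`).
#' @export
build_cpf <- function(results, bins = similarity_bins()) {
  if (is.null(results$max_train_similarity))
    stop("results lack a max_train_similarity column; ",
         "run the protocol with with_similarity = TRUE")
  error_cpf(results$rel_error_pct, results$max_train_similarity, bins)
}

#' @export
print.error_cpf <- function(x, ...) {
  cat("Similarity-conditioned error CPF\n")
  for (lab in rev(x$bins$label)) {
    n <- x$sizes[[lab]]
    if (n > 0L)
      cat(sprintf("  %-10s n = %5d  median error %6.2f %%\n",
                  lab, n, median(x$errors[[lab]])))
    else
      cat(sprintf("  %-10s n =     0  (unqueryable)\n", lab))
  }
  invisible(x)
}

#' Probability that the prediction error is below a threshold
#'
#' Looks up the similarity range of the query and returns the fraction of
#' that range's observed errors strictly below the threshold (set
#' `strict = FALSE` for "at or below").
#'
#' @param cpf An [error_cpf()].
#' @param similarity Query similarity in `[0, 1]`.
#' @param threshold Error threshold in percent.
#' @param strict Use strict inequality (default) or `<=`.
#' @return Probability in `[0, 1]`.
#' @export
error_probability <- function(cpf, similarity, threshold, strict = TRUE) {
  lab <- as.character(assign_bin(similarity, cpf$bins))
  errs <- cpf$errors[[lab]]
  if (is.null(errs) || length(errs) == 0L)
    stop("similarity range ", lab, " holds no observed errors; ",
         "evaluate the model on more data before querying it")
  if (strict) mean(errs < threshold) else mean(errs <= threshold)
}

#' @rdname error_probability
#' @export
predict.error_cpf <- function(object, similarity, threshold, strict = TRUE,
                              ...) {
  mapply(function(s, t) error_probability(object, s, t, strict),
         similarity, threshold)
}

#' Median observed error per similarity range
#'
#' @param cpf An [error_cpf()].
#' @return Named numeric vector (NA for unqueryable ranges), ordered from
#'   the lowest to the highest similarity range.
#' @export
bin_error_medians <- function(cpf) {
  vapply(cpf$bins$label, function(lab) {
    errs <- cpf$errors[[lab]]
    if (is.null(errs) || length(errs) == 0L) NA_real_ else median(errs)
  }, numeric(1))
}

#' Pairwise rank tests between similarity ranges
#'
#' Unpaired two-sided Mann-Whitney-Wilcoxon tests between every pair of
#' ranges, on error vectors first balanced to a common size.
#'
#' @param cpf An [error_cpf()] with data in every range.
#' @param rng_seed Seed for the balancing subsample.
#' @return Symmetric matrix of p-values.
#' @export
bin_pairwise_tests <- function(cpf, rng_seed = 1L) {
  groups <- balanced_subsample(cpf$errors[cpf$bins$label], rng_seed)
  k <- length(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { p[i, j] <- 1; next }
    p[i, j] <- stats::wilcox.test(groups[[i]], groups[[j]],
                                  exact = FALSE)$p.value
  }
  p
}

#' Plot the error CPF per similarity range
#'
#' @param x An [error_cpf()].
#' @param xlim Error axis range in percent.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.error_cpf <- function(x, xlim = c(0, 10), ...) {
  graphics::plot(NA, xlim = xlim, ylim = c(0, 1),
                 xlab = "relative RI error (%)",
                 ylab = "P(error < threshold)", ...)
  cols <- seq_len(nrow(x$bins))
  for (i in rev(seq_len(nrow(x$bins)))) {
    errs <- x$errors[[x$bins$label[i]]]
    if (length(errs) == 0L) next
    grid <- seq(xlim[1], xlim[2], length.out = 200)
    graphics::lines(grid, vapply(grid, function(t) mean(errs < t),
                                 numeric(1)), col = cols[i])
  }
  graphics::legend("bottomright", legend = rev(x$bins$label),
                   col = rev(cols), lty = 1, cex = 0.8)
  invisible(x)
}
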