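#' Expected Benford first-digit frequencies
#'
#' The Benford (first-digit) law predicts that the leading significant digit
#' \eqn{d \in \{1,\dots,9\}} of values in many count-rich datasets occurs with
#' probability \eqn{E_d = \log_{10}(1 + 1/d)}, so digit 1 leads about 30.1\%
#' of the time and the probabilities decrease strictly with \eqn{d}.
#'
#' @return A named numeric vector of length 9 (names `"1"`..`"9"`) summing to 1.
#' @examples
#' benford_expected()["1"] # 0.30103
#' @export
benford_expected <- function() {
  d <- 1:9
  stats::setNames(log10(1 + 1 / d), as.character(d))
}

#' First significant digit of positive numbers
#'
#' Returns the leftmost non-zero digit of the decimal representation of each
#' value, e.g. 2 for both 234 and 0.0023. Extraction uses power-of-ten
#' arithmetic with a guard re-check near decade boundaries, so values such as
#' `999.9999999` (whose `log10` rounds up to 3) are still classified by their
#' true leading digit.
#'
#' @param x Numeric vector of strictly positive, finite values. Zeros are not
#'   accepted here; callers tally and exclude them (see
#'   [digit_distribution()]).
#' @return Integer vector of digits in 1..9.
#' @examples
#' first_digit(c(345, 0.0023, 1e6)) # 3 2 1
#' @export
first_digit <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (length(x) == 0L) return(integer(0))
  if (anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("first_digit() requires strictly positive finite values", call. = FALSE)
  }
  e <- floor(log10(x))
  m <- x / 10^e
  # guard: floating log10 can land one decade off at powers of ten
  low <- m < 1
  if (any(low)) {
    e[low] <- e[low] - 1
    m[low] <- x[low] / 10^e[low]
  }
  high <- m >= 10
  if (any(high)) {
    e[high] <- e[high] + 1
    m[high] <- x[high] / 10^e[high]
  }
  as.integer(m)
}

#' Tabulate the first-digit distribution of a value collection
#'
#' Zeros are always excluded (an unexpressed gene carries no leading digit)
#' and tallied separately. With `exclude_below_one = TRUE`, values in (0, 1)
#' — typical of CPM-scaled low-expression genes, whose leading digits reflect
#' the scaling rather than the counts — are excluded and tallied as well.
#'
#' @param values Numeric vector of non-negative finite values. A negative
#'   value signals corrupt expression input and is an error, not an exclusion.
#' @param exclude_below_one Logical; drop values in (0, 1) before digit
#'   extraction. Default `FALSE`.
#' @return An object of class `digit_distribution`: a list with `counts` and
#'   `frequencies` (named numeric, digits 1..9), `n_used`, `n_excluded_zero`
#'   and `n_excluded_below_one`. When no usable values remain, `n_used` is 0
#'   and the frequencies are `NA` — an explicitly undefined distribution, not
#'   a silent zero vector.
#' @examples
#' digit_distribution(c(0, 0, 5))$counts
#' digit_distribution(c(0.5, 15), exclude_below_one = TRUE)$n_excluded_below_one
#' @export
digit_distribution <- function(values, exclude_below_one = FALSE) {
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite and non-missing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("negative values are not valid expression measurements", call. = FALSE)
  }
  is_zero <- values == 0
  below_one <- !is_zero & values < 1
  if (exclude_below_one) {
    usable <- values[!is_zero & !below_one]
    n_below <- sum(below_one)
  } else {
    usable <- values[!is_zero]
    n_below <- 0L
  }
  counts <- stats::setNames(tabulate(first_digit(usable), nbins = 9), as.character(1:9))
  n_used <- length(usable)
  freqs <- if (n_used > 0L) counts / n_used else stats::setNames(rep(NA_real_, 9), as.character(1:9))
  structure(
    list(
      counts = counts,
      frequencies = freqs,
      n_used = n_used,
      n_excluded_zero = sum(is_zero),
      n_excluded_below_one = as.integer(n_below)
    ),
    class = "digit_distribution"
  )
}

#' @export
print.digit_distribution <- function(x, ...) {
  cat("First-digit distribution:", x$n_used, "usable values",
      sprintf("(%d zero, %d below one excluded)\n",
              x$n_excluded_zero, x$n_excluded_below_one))
  if (x$n_used > 0L) print(round(x$frequencies, 4)) else cat("frequencies undefined\n")
  invisible(x)
}

#' Mean absolute error from the Benford distribution
#'
#' The conformity statistic \eqn{MAE = \frac{1}{9}\sum_{d=1}^{9} |A_d - E_d|},
#' where \eqn{A_d} are observed and \eqn{E_d} expected first-digit
#' frequencies. Lower values indicate closer adherence to the Benford law;
#' the statistic is bounded by the total-variation limit \eqn{2/9}.
#'
#' @param observed A [digit_distribution()] object, or a numeric vector of
#'   nine observed frequencies summing to 1.
#' @param reference Expected frequencies; defaults to [benford_expected()].
#' @return A single non-negative number in \[0, 2/9\].
#' @examples
#' benford_mae(digit_distribution(c(1, 10, 13, 150, 2, 3000)))
#' @export
benford_mae <- function(observed, reference = benford_expected()) {
  freqs <- .digit_frequencies(observed)
  mean(abs(freqs - reference))
}

#' Pearson chi-squared goodness-of-fit test against the Benford law
#'
#' Tests the observed first-digit counts against the Benford probabilities
#' with a 9-category Pearson goodness-of-fit test (8 degrees of freedom),
#' through [stats::chisq.test()]. Under the convention used for conformity
#' screening, a p-value above 0.05 is read as adherence to the law.
#'
#' @param observed A [digit_distribution()] object with `n_used > 0`.
#' @param reference Expected frequencies; defaults to [benford_expected()].
#' @return A list with `statistic`, `p_value` and `df` (always 8).
#' @export
benford_chisq <- function(observed, reference = benford_expected()) {
  if (!inherits(observed, "digit_distribution")) {
    stop("`observed` must be a digit_distribution (counts are required)", call. = FALSE)
  }
  if (observed$n_used == 0L) {
    stop("chi-squared test undefined: no usable values (n_used = 0)", call. = FALSE)
  }
  # expected cell counts below 5 only trigger chisq.test's approximation
  # warning; the statistic itself is what we report
  res <- suppressWarnings(
    stats::chisq.test(x = observed$counts, p = reference, rescale.p = FALSE)
  )
  list(
    statistic = unname(res$statistic),
    p_value = unname(res$p.value),
    df = unname(res$parameter)
  )
}

# Accepts a digit_distribution or a bare length-9 frequency vector; errors on
# an undefined (n_used = 0) distribution so NA never propagates silently.
.digit_frequencies <- function(observed) {
  if (inherits(observed, "digit_distribution")) {
    if (observed$n_used == 0L) {
      stop("MAE undefined: no usable values (n_used = 0); filter such genes deliberately",
           call. = FALSE)
    }
    return(observed$frequencies)
  }
  if (is.numeric(observed) && length(observed) == 9L) {
    if (anyNA(observed)) stop("frequencies contain NA", call. = FALSE)
    return(observed)
  }
  stop("`observed` must be a digit_distribution or nine frequencies", call. = FALSE)
}
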