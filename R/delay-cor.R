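#' Spearman co-expression score
#'
#' The co-expression score gamma of two expression profiles is the
#' Spearman rank correlation: the product-moment correlation of their
#' average (fractional) ranks.  Without ties this equals
#' \deqn{1 - 6 \sum d_i^2 / (L^3 - L)}
#' where \eqn{d_i} is the rank difference at condition \eqn{i} and
#' \eqn{L} the common length; average ranks are the standard
#' generalization when ties are present.  Indices where either profile
#' is missing are excluded pairwise.
#'
#' @param x,y numeric vectors of equal length; at least 3 jointly
#'   observed values are required.
#' @return the score in \[-1, 1\].
#' @section Errors: a profile that is constant over the jointly observed
#'   conditions has no defined rank correlation; the error condition
#'   class `delaycor_untestable` is signalled so callers can report the
#'   pair as untestable rather than coerce a p-value.
#' @examples
#' spearman_gamma(1:6, c(1, 3, 2, 4, 6, 5))  # 1 - 6*4/210
#' @export
spearman_gamma <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  L <- length(x)
  if (L < 3L)
    stop_untestable("fewer than 3 jointly observed conditions")
  .gamma_core(x, y, L)
}

## rank + moment correlation on average ranks; assumes clean equal-length
## finite input.  Hot path for the permutation null, so sums are done
## inline instead of calling cor().
.gamma_core <- function(x, y, L = length(x)) {
  rx <- rank(x)
  ry <- rank(y)
  if (!anyDuplicated(rx) && !anyDuplicated(ry)) {
    d <- rx - ry              # tie-free: the classical formula is exact
    return(1 - 6 * sum(d * d) / (L^3 - L))
  }
  mr <- (L + 1) / 2           # mean of average ranks, ties or not
  dx <- rx - mr
  dy <- ry - mr
  vx <- sum(dx * dx)
  vy <- sum(dy * dy)
  if (vx == 0 || vy == 0)
    stop_untestable("constant profile: rank correlation undefined")
  sum(dx * dy) / sqrt(vx * vy)
}

stop_untestable <- function(msg) {
  stop(structure(class = c("delaycor_untestable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

is_untestable_error <- function(e) inherits(e, "delaycor_untestable")

#' Truncate and shift a profile pair
#'
#' For a candidate delay of `t` ordered conditions the two profiles are
#' truncated to their overlap: with `direction = "x_delayed"` the pair
#' becomes `(x[(t+1):N], y[1:(N-t)])` (x trails y by t conditions) and
#' with `"y_delayed"` the mirror image.  `t = 0` leaves both untouched.
#' The overlap must keep at least 3 conditions.
#'
#' @param x,y numeric vectors of equal length `N`.
#' @param t integer shift, `0 <= t <= N - 3`.
#' @param direction `"none"` (only for `t = 0`), `"x_delayed"` or
#'   `"y_delayed"`.
#' @return a `shifted_pair` list: `x`, `y`, `t`, `direction`, `L`.
#' @export
shift_vectors <- function(x, y, t = 0L,
                          direction = c("none", "x_delayed", "y_delayed")) {
  direction <- match.arg(direction)
  N <- length(x)
  if (length(y) != N) stop("'x' and 'y' must have equal length", call. = FALSE)
  t <- as.integer(t)
  if (t < 0L) stop("'t' must be >= 0", call. = FALSE)
  if (t == 0L && direction != "none")
    stop("t = 0 implies direction 'none'", call. = FALSE)
  if (t > 0L && direction == "none")
    stop("a nonzero shift needs a direction", call. = FALSE)
  if (N - t < 3L)
    stop("infeasible shift: overlap ", N - t, " < 3 for t = ", t,
         call. = FALSE)
  if (t > 0L) {
    if (direction == "x_delayed") {
      x <- x[(t + 1L):N]; y <- y[1L:(N - t)]
    } else {
      x <- x[1L:(N - t)]; y <- y[(t + 1L):N]
    }
  }
  structure(list(x = x, y = y, t = t, direction = direction,
                 L = N - t),
            class = "shifted_pair")
}

## index pairs for every admissible shift, in tie-break preference order:
## smaller t first; within a t, none, then x_delayed, then y_delayed.
shift_table <- function(N, max_delay, ordered = TRUE) {
  if (!ordered) max_delay <- 0L
  max_delay <- as.integer(max_delay)
  if (max_delay < 0L) stop("'max_delay' must be >= 0", call. = FALSE)
  if (N - max_delay < 3L)
    stop("infeasible shift: overlap ", N - max_delay, " < 3 for max_delay = ",
         max_delay, call. = FALSE)
  out <- list(list(t = 0L, direction = "none",
                   ix = seq_len(N), iy = seq_len(N)))
  for (t in seq_len(max_delay)) {
    out[[length(out) + 1L]] <- list(t = t, direction = "x_delayed",
                                    ix = (t + 1L):N, iy = 1L:(N - t))
    out[[length(out) + 1L]] <- list(t = t, direction = "y_delayed",
                                    ix = 1L:(N - t), iy = (t + 1L):N)
  }
  out
}

#' Scan all admissible delays of a profile pair
#'
#' Evaluates the co-expression score at shift 0 and at every shift
#' `1..max_delay` in both directions (`2 * max_delay + 1` records for
#' ordered data).  For unordered sample panels no delay is meaningful
#' and `max_delay` is forced to 0.  The predicted delay is the shift
#' with the highest absolute score; ties prefer the smaller shift, and
#' within a shift the order none, x_delayed, y_delayed (the most
#' parsimonious claim).  Selection uses |gamma| because strong negative
#' correlation also counts as co-expression.
#'
#' @inheritParams shift_vectors
#' @param max_delay largest shift to examine; the overlap rule requires
#'   `max_delay <= length(x) - 3`.
#' @param ordered logical; `FALSE` forces `max_delay = 0`.
#' @return a `delay_scan`: data.frame `records` (`t`, `direction`,
#'   `gamma`; `NA` gamma where the truncated pair is untestable) plus
#'   `best_t`, `best_direction`, `best_gamma`, `n_shifts`.
#' @section Errors: if every shift is untestable the
#'   `delaycor_untestable` condition is signalled.
#' @export
scan_delays <- function(x, y, max_delay = 3L, ordered = TRUE) {
  shifts <- shift_table(length(x), max_delay, ordered)
  gam <- vapply(shifts, function(s) {
    tryCatch(spearman_gamma(x[s$ix], y[s$iy]),
             delaycor_untestable = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(gam)))
    stop_untestable("pair untestable at every shift")
  best <- which.max(abs(gam))  # first maximum = preference order
  structure(list(
    records = data.frame(
      t = vapply(shifts, `[[`, integer(1), "t"),
      direction = vapply(shifts, `[[`, character(1), "direction"),
      gamma = gam, stringsAsFactors = FALSE),
    best_t = shifts[[best]]$t,
    best_direction = shifts[[best]]$direction,
    best_gamma = gam[best],
    n_shifts = length(shifts)), class = "delay_scan")
}

#' @export
print.delay_scan <- function(x, ...) {
  cat(sprintf("Delay scan (%d shifts): best gamma = %.4f at t = %d (%s)\n",
              x$n_shifts, x$best_gamma, x$best_t, x$best_direction))
  print(x$records, row.names = FALSE, ...)
  invisible(x)
}
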