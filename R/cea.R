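#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Compares an intervention with a comparator.  When the intervention
#' gains QALYs at extra cost the ICER \eqn{\Delta cost / \Delta QALY} is
#' returned; otherwise the sign pattern is classified: `"dominant"` when
#' it is at least as effective and no more costly (and not identical),
#' `"dominated"` when it is less effective and more costly (or equally
#' effective but more costly), `"indifferent"` when both deltas are zero,
#' and `"icer"` otherwise (including the cost-saving, QALY-losing
#' south-west quadrant, where the ICER is a savings-per-QALY-forgone
#' ratio).
#'
#' @param intervention,comparator Numeric vectors `c(cost, qaly)` or lists
#'   with `cost` and `qaly` elements.
#' @return A list with `delta_cost`, `delta_qaly`, `status` and `icer`
#'   (`NA` unless status is `"icer"`).
#' @export
icer <- function(intervention, comparator) {
  iv <- as_cost_qaly(intervention)
  cp <- as_cost_qaly(comparator)
  dc <- iv[["cost"]] - cp[["cost"]]
  dq <- iv[["qaly"]] - cp[["qaly"]]
  if (!all(is.finite(c(dc, dq)))) stop("inputs must be finite", call. = FALSE)
  status <-
    if (dc == 0 && dq == 0) "indifferent"
    else if (dq >= 0 && dc <= 0) "dominant"
    else if ((dq < 0 && dc > 0) || (dq == 0 && dc > 0)) "dominated"
    else "icer"
  list(delta_cost = dc, delta_qaly = dq, status = status,
       icer = if (status == "icer") dc / dq else NA_real_)
}

as_cost_qaly <- function(x) {
  if (is.list(x)) x <- c(cost = x$cost, qaly = x$qaly)
  if (is.null(names(x))) names(x) <- c("cost", "qaly")
  x
}

#' Net monetary benefit
#'
#' \eqn{NMB = WTP \times QALY - cost}.
#'
#' @param cost,qaly Strategy totals (vectorised).
#' @param wtp Willingness-to-pay in $/QALY, non-negative.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative", call. = FALSE)
  wtp * qaly - cost
}

#' Cost-effectiveness efficiency frontier
#'
#' Sorts strategies by cost, removes strictly dominated strategies (a
#' cheaper strategy with at least the same QALYs exists) and extendedly
#' dominated ones (sequential ICERs not strictly increasing), and returns
#' the efficient set with the ICER of each member versus the previous
#' frontier member.
#'
#' @param strategies Data frame with columns `name`, `cost`, `qaly`.
#' @return The efficient subset with an added `icer` column (`NA` for the
#'   cheapest member).
#' @export
frontier <- function(strategies) {
  stopifnot(nrow(strategies) >= 1,
            all(c("name", "cost", "qaly") %in% names(strategies)))
  s <- strategies[order(strategies$cost, strategies$qaly), , drop = FALSE]
  # strict dominance: drop any strategy with a no-more-costly,
  # at-least-as-effective alternative (other than itself)
  keep <- vapply(seq_len(nrow(s)), function(i) {
    !any(s$cost <= s$cost[i] & s$qaly >= s$qaly[i] &
           (s$cost < s$cost[i] | s$qaly > s$qaly[i]))
  }, logical(1))
  s <- s[keep, , drop = FALSE]
  # extended dominance: sequential ICERs must be strictly increasing;
  # equal sequential ICERs (collinear strategies) are retained
  repeat {
    if (nrow(s) < 3) break
    ic <- diff(s$cost) / diff(s$qaly)
    bad <- which(diff(ic) < 0)
    if (length(bad) == 0) break
    s <- s[-(bad[1] + 1L), , drop = FALSE]
  }
  s$icer <- c(NA_real_, diff(s$cost) / diff(s$qaly))
  rownames(s) <- NULL
  s
}

#' Pairwise cost-effectiveness results table
#'
#' Builds the base-case results block: per-strategy totals plus the
#' pairwise incremental comparisons the model reports.
#'
#' @param strategies Data frame with columns `name`, `cost`, `qaly`.
#' @param pairs List of `c(intervention, comparator)` name pairs; default
#'   compares every strategy with the first (cheapest-listed) one and
#'   consecutive pairs.
#' @return A list with `totals` (the input, cost-sorted) and
#'   `incremental` (one row per pair: deltas, status, ICER).
#' @export
cea_table <- function(strategies, pairs = NULL) {
  stopifnot(all(c("name", "cost", "qaly") %in% names(strategies)))
  if (is.null(pairs)) {
    nm <- strategies$name
    pairs <- list()
    if (length(nm) >= 2) {
      pairs <- c(lapply(nm[-1], function(x) c(x, nm[1])))
      if (length(nm) >= 3) {
        pairs <- c(lapply(seq_len(length(nm) - 2L) + 2L,
                          function(i) c(nm[i], nm[i - 1L])), pairs)
      }
    }
  }
  inc <- do.call(rbind, lapply(pairs, function(p) {
    a <- strategies[strategies$name == p[1], ]
    b <- strategies[strategies$name == p[2], ]
    stopifnot(nrow(a) == 1, nrow(b) == 1)
    r <- icer(c(a$cost, a$qaly), c(b$cost, b$qaly))
    data.frame(intervention = p[1], comparator = p[2],
               delta_cost = r$delta_cost, delta_qaly = r$delta_qaly,
               status = r$status, icer = r$icer)
  }))
  list(totals = strategies[order(strategies$cost), , drop = FALSE],
       incremental = inc)
}
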