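#' Probability that two identifications did not overlap in a cluster
#'
#' Closed-form probability that two individuals identified `lag` ordinal
#' units apart were never simultaneously present in the same observable
#' ("photographable") cluster, under the assumption that individuals leave
#' the cluster independently at rate `mu` per ordinal unit and that
#' immigration and emigration rates are approximately equal:
#' \deqn{P(\mathrm{no\ overlap}) = 1 - (1 + \mu T)\,e^{-\mu T}.}
#'
#' @param lag non-negative lag(s) between the two identifications, in
#'   ordinal units (frames, seconds).
#' @param mu emigration rate from the observable cluster, per ordinal unit
#'   per individual (strictly positive). The mean residence time in the
#'   cluster is `1/mu`.
#' @return numeric vector of probabilities in `[0, 1]`, increasing in `lag`.
#' @seealso [prob_overlap()], [lir_model()]
#' @examples
#' prob_no_overlap(0, 1)        # 0: zero lag, certainly together
#' prob_no_overlap(1, 1)        # 1 - 2/e
#' @export
prob_no_overlap <- function(lag, mu) {
  check_lag_mu(lag, mu)
  1 - (1 + mu * lag) * exp(-mu * lag)
}

#' Probability that two identifications overlapped in a cluster
#'
#' Complement of [prob_no_overlap()]: the probability that two individuals
#' identified `lag` ordinal units apart were together in the same observable
#' cluster at some intervening moment,
#' \deqn{P(\mathrm{overlap}) = (1 + \mu T)\,e^{-\mu T}.}
#' At a lag equal to the mean residence time (`lag = 1/mu`) this equals
#' `2/e`, about 0.736, for every `mu` — the basis of the probabilistic
#' association threshold.
#'
#' @inheritParams prob_no_overlap
#' @return numeric vector of probabilities in `[0, 1]`, decreasing in `lag`;
#'   equals 1 at `lag = 0`.
#' @examples
#' prob_overlap(1 / 0.2, 0.2)   # ~0.736 regardless of mu
#' @export
prob_overlap <- function(lag, mu) {
  check_lag_mu(lag, mu)
  (1 + mu * lag) * exp(-mu * lag)
}

check_lag_mu <- function(lag, mu) {
  if (any(!is.finite(lag)) || any(lag < 0))
    stop("`lag` must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("`mu` must be finite and strictly positive", call. = FALSE)
  invisible(NULL)
}

#' Emigration + reimmigration model of the lagged identification rate
#'
#' Expected lagged identification rate at lag `T` for a population of `a`
#' individuals using an observable cluster, with mean residence time `b`
#' inside the cluster and mean time `c` outside it before reimmigrating:
#' \deqn{R(T) = \frac{1}{a}\,
#'   \frac{1/c + (1/b)\,e^{-(1/b + 1/c)T}}{1/b + 1/c}.}
#' `R(0) = 1/a` and `R(T)` decays monotonically to the asymptote
#' `(1/a) b/(b + c)`.
#'
#' @param lag non-negative lag(s) in ordinal units.
#' @param a effective number of individuals in the focus area (> 0, need
#'   not be an integer).
#' @param b mean residence time inside the observable cluster, ordinal
#'   units (> 0).
#' @param c_out mean time outside the cluster before reimmigration, ordinal
#'   units (> 0).
#' @return expected identification rate(s) in `(0, 1/a]`.
#' @examples
#' lir_model(0, a = 10, b = 5, c_out = 20)    # 1/a = 0.1
#' lir_model(1e6, a = 10, b = 5, c_out = 20)  # asymptote b/(a*(b+c)) = 0.02
#' @export
lir_model <- function(lag, a, b, c_out) {
  if (any(!is.finite(lag)) || any(lag < 0))
    stop("`lag` must be finite and non-negative", call. = FALSE)
  if (!all(is.finite(c(a, b, c_out))) || any(c(a, b, c_out) <= 0))
    stop("`a`, `b` and `c_out` must be finite and strictly positive",
         call. = FALSE)
  lam <- 1 / b + 1 / c_out
  (1 / a) * (1 / c_out + (1 / b) * exp(-lam * lag)) / lam
}

#' Probabilistic association threshold from a mean residence time
#'
#' Converts a fitted mean residence time `b` (ordinal units inside an
#' observable cluster) into the integer association threshold: two
#' identifications within this many ordinal units of each other are treated
#' as evidence the individuals overlapped in a cluster. At the unrounded
#' threshold `T = b` the overlap probability is `2/e`, about 0.736 ("an
#' almost 75% probability"). The integer threshold is `b` rounded half-up,
#' floored at 1 ordinal unit (a zero threshold would forbid all
#' associations; ordinal lags are integers for frame-numbered data).
#'
#' @param b mean residence time in the observable cluster (> 0), ordinal
#'   units; typically the `b` parameter of a fitted [lir_model()].
#' @return an object of class `"assoc_threshold"`: a list with `threshold`
#'   (integer, >= 1), `b_raw` (the unrounded input), `overlap_at_threshold`
#'   (overlap probability evaluated at the integer threshold with
#'   `mu = 1/b`) and `overlap_at_b` (`2/e`, the probability at the
#'   unrounded threshold).
#' @examples
#' association_threshold(14.2)   # threshold 14
#' association_threshold(0.4)    # floored to 1
#' @export
association_threshold <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("`b` must be a single finite positive number", call. = FALSE)
  thr <- max(1L, as.integer(floor(b + 0.5)))
  structure(
    list(threshold = thr,
         b_raw = b,
         overlap_at_threshold = prob_overlap(thr, 1 / b),
         overlap_at_b = prob_overlap(b, 1 / b)),
    class = "assoc_threshold"
  )
}

#' @export
print.assoc_threshold <- function(x, ...) {
  cat(sprintf(
    "Probabilistic association threshold: %d ordinal units\n", x$threshold))
  cat(sprintf("  mean residence time b = %.3f\n", x$b_raw))
  cat(sprintf("  P(overlap) at threshold = %.3f (%.3f at unrounded b)\n",
              x$overlap_at_threshold, x$overlap_at_b))
  invisible(x)
}
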