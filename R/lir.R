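#' Composite ordinal keying identifications by collection event
#'
#' Spreads collection events apart on a single ordinal axis so that lags are
#' only computable within an event: `ordinal + event_index * offset`. With
#' ordinals rebased to each event's first frame and `offset` exceeding
#' twice the maximum within-event lag, every cross-event pair of
#' identifications has a composite lag larger than any within-event lag and
#' is excluded by the maximum-lag rule downstream.
#'
#' @param ordinal numeric ordinal clock value(s) within the event.
#' @param event_index integer event index(es), 0-based or any consecutive
#'   coding; recycled against `ordinal`.
#' @param offset single number comfortably exceeding the maximum
#'   within-event lag in the dataset (e.g. 10,000 for frame-numbered data
#'   where no encounter spans more than a few thousand frames).
#' @return numeric composite ordinals.
#' @examples
#' keyed_ordinal(35, 2, 10000)  # 20035
#' @export
keyed_ordinal <- function(ordinal, event_index, offset) {
  if (length(offset) != 1L || !is.finite(offset) || offset <= 0)
    stop("`offset` must be a single positive number", call. = FALSE)
  ordinal + event_index * offset
}

# Default offset: smallest power of 10 strictly exceeding twice the
# maximum within-event lag (rebased events span [0, max_lag], so any
# cross-event composite lag is at least offset - max_lag > max_lag).
auto_offset <- function(max_lag) {
  10^(floor(log10(max(2 * max_lag, 1))) + 1)
}

# Composite ordinals for a record table; ordinals are rebased to each
# event's first frame and events mapped to consecutive 0-based integer
# indices in order of first appearance.
composite_ordinals <- function(records, offset = "auto",
                               max_lag = NULL) {
  if (is.null(max_lag)) max_lag <- max_within_event_lag(records)
  if (identical(offset, "auto")) offset <- auto_offset(max_lag)
  if (offset <= 2 * max_lag)
    stop(sprintf(
      "offset (%g) must exceed twice the maximum within-event lag (%g); ",
      offset, max_lag),
      "a smaller offset could create spurious cross-event lags",
      call. = FALSE)
  ord0 <- records$ordinal -
    stats::ave(records$ordinal, records$event, FUN = min)
  ev_index <- match(records$event, unique(records$event)) - 1L
  list(composite = keyed_ordinal(ord0, ev_index, offset),
       offset = offset, max_lag = max_lag)
}

#' Empirical lagged identification rate within collection events
#'
#' Estimates, for each lag `tau` (0 < `tau` <= `max_lag`), the proportion of
#' unordered pairs of identifications `tau` ordinal units apart that name
#' the same individual. Lags are computed on the composite ordinal
#' ([keyed_ordinal()]), so only pairs within the same collection event
#' contribute; `max_lag` defaults to the maximum lag observed within any
#' single event. Same-ordinal pairs (lag 0) carry no decay information and
#' are excluded.
#'
#' @param records identification records (see [read_identifications()]); a
#'   `date` column is not required for this computation.
#' @param max_lag maximum lag considered, ordinal units; `NULL` (default)
#'   uses the maximum within-event lag in the data.
#' @param offset event offset for the composite ordinal; `"auto"` (default)
#'   picks the smallest power of 10 exceeding twice `max_lag`.
#' @param binning `"unit"` for unit-lag resolution (non-integer lags are
#'   assigned to the bin `ceiling(lag)`), or `"log"` for logarithmically
#'   spaced bins (useful for sparse data).
#' @param n_bins number of bins when `binning = "log"`.
#' @return an object of class `"lir_curve"`: a data.frame with columns
#'   `lag` (lag or bin midpoint), `m` (same-individual pairs), `n` (all
#'   pairs) and `rate` (`m/n`), with attributes `max_lag`, `offset`,
#'   `binning` and `n_records`.
#' @examples
#' rec <- data.frame(individual = c("A", "A", "B"),
#'                   event = "e1", ordinal = c(1, 3, 3))
#' empirical_lir(rec)   # rate 0.5 at lag 2
#' @export
empirical_lir <- function(records, max_lag = NULL, offset = "auto",
                          binning = c("unit", "log"), n_bins = 20L) {
  binning <- match.arg(binning)
  records <- validate_records(records, require_date = FALSE)
  if (nrow(records) < 2L)
    stop("need at least two identification records", call. = FALSE)
  co <- composite_ordinals(records, offset = offset, max_lag = max_lag)
  max_lag <- if (is.null(max_lag)) co$max_lag else max_lag
  if (max_lag < 1)
    stop("`max_lag` must be at least 1 ordinal unit", call. = FALSE)

  ord <- order(co$composite)
  v <- co$composite[ord]
  id <- records$individual[ord]
  n_rec <- length(v)

  # two-pointer sweep over the sorted composite axis: for each record, all
  # later records within max_lag form candidate pairs
  upper <- findInterval(v + max_lag, v)
  lag_list <- vector("list", n_rec)
  same_list <- vector("list", n_rec)
  for (i in seq_len(n_rec - 1L)) {
    hi <- upper[i]
    if (hi <= i) next
    js <- (i + 1L):hi
    lags <- v[js] - v[i]
    keep <- lags > 0
    if (!any(keep)) next
    lag_list[[i]] <- lags[keep]
    same_list[[i]] <- id[js][keep] == id[i]
  }
  lags <- unlist(lag_list, use.names = FALSE)
  same <- unlist(same_list, use.names = FALSE)
  if (length(lags) == 0L)
    stop("no positive lags within max_lag: degenerate ordinal clock",
         call. = FALSE)

  if (binning == "unit") {
    bin <- as.integer(ceiling(lags))
    n_tau <- tabulate(bin, nbins = as.integer(ceiling(max_lag)))
    m_tau <- tabulate(bin[same], nbins = as.integer(ceiling(max_lag)))
    lag_val <- seq_along(n_tau)
  } else {
    breaks <- unique(c(0, exp(seq(log(1), log(max_lag),
                                  length.out = n_bins))))
    breaks[length(breaks)] <- max_lag
    bin <- findInterval(lags, breaks, left.open = TRUE,
                        rightmost.closed = TRUE)
    nb <- length(breaks) - 1L
    n_tau <- tabulate(bin, nbins = nb)
    m_tau <- tabulate(bin[same], nbins = nb)
    lag_val <- sqrt(pmax(breaks[-length(breaks)], 0.5) * breaks[-1])
  }
  keep <- n_tau > 0L
  curve <- data.frame(lag = lag_val[keep], m = m_tau[keep], n = n_tau[keep])
  curve$rate <- curve$m / curve$n
  structure(curve,
            max_lag = max_lag, offset = co$offset, binning = binning,
            n_records = n_rec,
            class = c("lir_curve", "data.frame"))
}

#' @export
print.lir_curve <- function(x, ...) {
  cat(sprintf(
    "Lagged identification rate: %d lag bins, %d pairs, max lag %g\n",
    nrow(x), sum(x$n), attr(x, "max_lag")))
  NextMethod()
}

#' Plot an empirical LIR curve, optionally with a fitted model
#'
#' @param x an `"lir_curve"` object.
#' @param fit optional `"residence_fit"` to overlay as a line.
#' @param ... passed to [plot()].
#' @export
plot.lir_curve <- function(x, fit = NULL, ...) {
  plot(x$lag, x$rate, pch = 16, cex = 0.6,
       xlab = "lag (ordinal units)", ylab = "lagged identification rate",
       ...)
  if (!is.null(fit)) {
    tt <- seq(0, max(x$lag), length.out = 400)
    lines(tt, lir_model(tt, fit$a, fit$b, fit$c_out))
    if (!is.null(fit$threshold))
      abline(v = fit$threshold$threshold, lty = 2)
  }
  invisible(x)
}

# evaluate the binomial log-likelihood of curve counts under (a, b, c)
lir_loglik <- function(curve, a, b, c_out, clip = 1e-9) {
  p <- lir_model(curve$lag, a, b, c_out)
  p <- pmin(pmax(p, clip), 1 - clip)
  sum(stats::dbinom(curve$m, curve$n, p, log = TRUE))
}

#' Fit the emigration + reimmigration model to an LIR curve
#'
#' Maximizes the binomial log-likelihood
#' \deqn{\sum_\tau \big[m(\tau)\log R(\tau) + (n(\tau)-m(\tau))
#'   \log(1-R(\tau))\big]}
#' over the parameters of [lir_model()] with multi-start Nelder--Mead on
#' log-transformed `(a, b, c)`. The fitted mean residence time `b` is
#' converted to the integer probabilistic association threshold via
#' [association_threshold()].
#'
#' @param curve an `"lir_curve"` from [empirical_lir()].
#' @param n_starts number of jittered starting points around a moment-based
#'   heuristic.
#' @param starts optional list of explicit `c(a, b, c_out)` start vectors,
#'   used instead of the jittered ones.
#' @param seed seed for start-point jitter (local to this call; the global
#'   RNG stream is left untouched).
#' @param subset_label optional label recorded in the fit (used by
#'   [fit_by_subset()]).
#' @return an object of class `"residence_fit"`: a list with elements `a`,
#'   `b`, `c_out`, `loglik`, `threshold` (an `"assoc_threshold"`, or `NULL`
#'   for non-informative fits), `n_pairs`, `converged`, `informative`,
#'   `clipped` and `subset_label`.
#' @export
fit_residence_model <- function(curve, n_starts = 8L, starts = NULL,
                                seed = 1L, subset_label = NA_character_) {
  stopifnot(inherits(curve, "lir_curve"))
  curve <- curve[curve$n > 0, , drop = FALSE]
  if (length(unique(curve$lag)) < 3L)
    stop("need at least 3 distinct lags with pairs to fit the model",
         call. = FALSE)
  max_lag <- max(curve$lag)

  # moment heuristic: intercept ~ 1/a, tail ~ asymptote
  r0 <- max(curve$rate[which.min(curve$lag)], 1e-6)
  tail_idx <- curve$lag >= stats::quantile(curve$lag, 0.8)
  r_inf <- sum(curve$m[tail_idx]) / max(sum(curve$n[tail_idx]), 1)
  r_inf <- min(max(r_inf, r0 * 1e-3), r0 * 0.95)
  a0 <- 1 / r0
  b0 <- max_lag / 4
  c0 <- b0 * max(r0 / r_inf - 1, 0.5)
  base <- log(c(a0, b0, c0))

  if (is.null(starts)) {
    jitter <- with_local_seed(seed, {
      matrix(stats::rnorm(3L * n_starts, sd = 1), ncol = 3L)
    })
    jitter[1, ] <- 0  # first start is the heuristic itself
    start_mat <- sweep(jitter, 2L, base, "+")
  } else {
    start_mat <- do.call(rbind, lapply(starts, log))
  }

  negll <- function(lp) {
    p <- exp(lp)
    if (any(!is.finite(p)) || any(p <= 0)) return(1e12)
    -lir_loglik(curve, p[1], p[2], p[3])
  }

  fits <- apply(start_mat, 1L, function(s) {
    tryCatch(stats::optim(s, negll, method = "Nelder-Mead",
                          control = list(maxit = 4000, reltol = 1e-12)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L)
    stop("model fitting failed from every start point", call. = FALSE)
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  pars <- exp(best$par)
  a <- pars[1]; b <- pars[2]; c_out <- pars[3]

  r_fit <- lir_model(curve$lag, a, b, c_out)
  clipped <- any(r_fit >= 1 - 1e-9)
  if (clipped)
    warning("fitted rate reaches 1 at some lags; likelihood was clipped",
            call. = FALSE)

  # a flat curve carries no decay signal: b is unbounded
  decay <- (lir_model(0, a, b, c_out) - lir_model(max_lag, a, b, c_out)) /
    lir_model(0, a, b, c_out)
  informative <- is.finite(b) && b <= 50 * max_lag && decay > 1e-3
  converged <- best$convergence == 0L

  structure(
    list(a = a, b = b, c_out = c_out,
         loglik = -best$value,
         threshold = if (informative) association_threshold(b) else NULL,
         n_pairs = sum(curve$n),
         converged = converged,
         informative = informative,
         clipped = clipped,
         subset_label = subset_label,
         start_values = -vals),
    class = "residence_fit"
  )
}

#' @export
print.residence_fit <- function(x, ...) {
  lab <- if (is.na(x$subset_label)) "" else sprintf(" [%s]", x$subset_label)
  cat(sprintf("Emigration + reimmigration LIR fit%s\n", lab))
  cat(sprintf("  a = %.3f, b = %.3f, c = %.3f (logLik %.2f, %d pairs)\n",
              x$a, x$b, x$c_out, x$loglik, x$n_pairs))
  if (!x$informative) {
    cat("  fit is non-informative (no decay signal); no threshold derived\n")
  } else {
    cat(sprintf("  association threshold: %d ordinal units (raw b %.2f)\n",
                x$threshold$threshold, x$threshold$b_raw))
  }
  invisible(x)
}

#' Fit the residence model separately within data subsets
#'
#' Partitions the records by an attribute column (e.g. `data_type` with
#' values film/digital, or `effort` dedicated/non-dedicated), computes each
#' partition's own LIR (its own maximum lag and offset) and fits the
#' residence model independently, so each subset gets the association
#' threshold its own collection process implies.
#'
#' @param records identification records carrying the attribute column.
#' @param attribute name of the attribute column to split on.
#' @param max_lag,offset,binning passed to [empirical_lir()] per subset.
#' @param ... passed to [fit_residence_model()].
#' @return named list of `"residence_fit"` objects, one per attribute value;
#'   subsets with too few informative lags are dropped with a message.
#' @export
fit_by_subset <- function(records, attribute, max_lag = NULL,
                          offset = "auto", binning = "unit", ...) {
  records <- validate_records(records, require_date = FALSE)
  if (!attribute %in% names(records))
    stop(sprintf("attribute column '%s' not found in records", attribute),
         call. = FALSE)
  parts <- split(records, records[[attribute]])
  fits <- list()
  for (lab in names(parts)) {
    fit <- tryCatch({
      cv <- empirical_lir(parts[[lab]], max_lag = max_lag, offset = offset,
                          binning = binning)
      fit_residence_model(cv, subset_label = lab, ...)
    }, error = function(e) {
      message(sprintf("subset '%s' skipped: %s", lab, conditionMessage(e)))
      NULL
    })
    if (!is.null(fit)) fits[[lab]] <- fit
  }
  fits
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
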