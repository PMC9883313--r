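#' Restrict analysis to regularly and persistently seen individuals
#'
#' Standard filter before association analysis: keep individuals seen on at
#' least `min_days` distinct sampling days and — to reduce bias from deaths,
#' births and transients — seen in every required year (typically the first
#' and last year of the study).
#'
#' @param records identification records with a `date` column.
#' @param min_days minimum number of distinct days an individual must have
#'   been identified on (default 5).
#' @param require_years integer vector of calendar years the individual must
#'   appear in (e.g. `c(1997, 2010)`); `NULL` to skip the year requirement.
#' @return character vector of retained individual IDs (possibly empty,
#'   with a warning).
#' @export
restrict_individuals <- function(records, min_days = 5L,
                                 require_years = NULL) {
  records <- validate_records(records)
  days_per_ind <- tapply(records$date, records$individual,
                         function(d) length(unique(d)))
  keep <- names(days_per_ind)[days_per_ind >= min_days]
  if (!is.null(require_years)) {
    yr <- as.integer(format(records$date, "%Y"))
    for (y in as.integer(require_years)) {
      seen_y <- unique(records$individual[yr == y])
      keep <- intersect(keep, seen_y)
    }
  }
  if (length(keep) == 0L)
    warning("no individuals pass the restriction filter", call. = FALSE)
  sort(keep)
}

# canonical dyad key "A|B" with A < B
dyad_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "|")
}

# dyads associated within one event under one criterion; returns a
# character vector of dyad keys
event_dyads <- function(ind, ord, criterion, threshold) {
  if (length(ind) < 2L) return(character(0))
  if (criterion == "encounter") {
    u <- unique(ind)
    if (length(u) < 2L) return(character(0))
    pairs <- utils::combn(sort(u), 2L)
    return(paste(pairs[1L, ], pairs[2L, ], sep = "|"))
  }
  o <- order(ord)
  ind <- ind[o]; ord <- ord[o]
  n <- length(ord)
  lim <- if (criterion == "same_frame") 0 else threshold
  upper <- findInterval(ord + lim, ord)
  keys <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    hi <- upper[i]
    if (hi <= i) next
    js <- (i + 1L):hi
    other <- ind[js][ind[js] != ind[i]]
    if (length(other) > 0L) keys[[i]] <- dyad_key(ind[i], other)
  }
  unique(unlist(keys, use.names = FALSE))
}

#' Daily dyadic associations under one of three criteria
#'
#' Scores every dyad once per sampling day (calendar date). Two individuals
#' are associated for the day if, at least once that day, they were:
#' \describe{
#'   \item{`probabilistic`}{identified in the same collection event with an
#'     ordinal lag of at most `threshold` units (the probabilistic
#'     association threshold, inclusive comparison);}
#'   \item{`same_frame`}{identified at the identical (event, ordinal)
#'     position — the same frame;}
#'   \item{`encounter`}{identified anywhere in the same collection event.}
#' }
#' The criteria are nested: same-frame associations are a subset of
#' probabilistic ones, which are a subset of encounter ones.
#'
#' @param records identification records.
#' @param criterion one of `"probabilistic"`, `"same_frame"`, `"encounter"`.
#' @param threshold integer association threshold in ordinal units; required
#'   for (and only used by) the probabilistic criterion.
#' @param ids optional vector of individual IDs to restrict to (e.g. from
#'   [restrict_individuals()]); other individuals' records are dropped.
#' @return an object of class `"association_data"`: a list with `days`
#'   (sorted Date vector), `seen` (per-day character vectors of identified
#'   individuals), `edges` (per-day two-column character matrices of
#'   associated dyads), `criterion`, `threshold` and `ids`.
#' @export
daily_associations <- function(records,
                               criterion = c("probabilistic", "same_frame",
                                             "encounter"),
                               threshold = NULL, ids = NULL) {
  criterion <- match.arg(criterion)
  records <- validate_records(records)
  if (criterion == "probabilistic") {
    if (is.null(threshold) || !is.finite(threshold) || threshold < 0)
      stop("the probabilistic criterion needs a non-negative `threshold`",
           call. = FALSE)
  } else {
    threshold <- NULL
  }
  if (!is.null(ids)) {
    records <- records[records$individual %in% ids, , drop = FALSE]
    if (nrow(records) == 0L)
      stop("no records left after restricting to `ids`", call. = FALSE)
  }
  days <- sort(unique(records$date))
  seen <- vector("list", length(days))
  edges <- vector("list", length(days))
  for (k in seq_along(days)) {
    day_rec <- records[records$date == days[k], , drop = FALSE]
    seen[[k]] <- sort(unique(day_rec$individual))
    keys <- unlist(lapply(split(day_rec, day_rec$event), function(ev)
      event_dyads(ev$individual, ev$ordinal, criterion, threshold)),
      use.names = FALSE)
    keys <- unique(keys)
    edges[[k]] <- if (length(keys) > 0L) {
      do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    } else {
      matrix(character(0), ncol = 2L)
    }
  }
  structure(
    list(days = days, seen = seen, edges = edges,
         criterion = criterion, threshold = threshold,
         ids = sort(unique(records$individual))),
    class = "association_data"
  )
}

#' @export
print.association_data <- function(x, ...) {
  cat(sprintf(
    "Daily associations (%s criterion%s): %d individuals, %d days, %d dyad-days\n",
    x$criterion,
    if (is.null(x$threshold)) "" else sprintf(", threshold %d", x$threshold),
    length(x$ids), length(x$days),
    sum(vapply(x$edges, nrow, integer(1)))))
  invisible(x)
}

#' Half-weight index matrix from daily associations
#'
#' Collapses per-day associations into the half-weight index for every dyad:
#' \deqn{\mathrm{HWI} = \frac{x}{x + y_{AB} + (y_A + y_B)/2}}
#' where, over sampling days, `x` counts days both individuals were
#' identified and associated, `yAB` days both identified but not associated,
#' and `yA`, `yB` days only one of them was identified. Dyads never jointly
#' sampled are flagged as structural zeros.
#'
#' @param assoc an `"association_data"` object.
#' @param ids optional ordered ID vector for the matrix (defaults to all
#'   individuals in `assoc`); individuals without records get all-zero rows.
#' @return an object of class `"hwi_matrix"`: a list with `hwi` (symmetric
#'   numeric matrix, zero diagonal), the tally matrices `x`, `yab`, `ya`,
#'   `yb`, `joint` (days jointly sampled), logical `structural_zero`, and
#'   `ids`.
#' @export
hwi_matrix <- function(assoc, ids = NULL) {
  stopifnot(inherits(assoc, "association_data"))
  if (is.null(ids)) ids <- assoc$ids
  ids <- sort(unique(as.character(ids)))
  n <- length(ids)
  n_days <- length(assoc$days)

  # day x individual incidence of being identified
  inc <- matrix(0L, nrow = n_days, ncol = n, dimnames = list(NULL, ids))
  for (k in seq_len(n_days)) {
    s <- intersect(assoc$seen[[k]], ids)
    inc[k, s] <- 1L
  }
  joint <- crossprod(inc)                    # days both seen
  seen_days <- diag(joint)

  x <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (k in seq_len(n_days)) {
    e <- assoc$edges[[k]]
    if (nrow(e) == 0L) next
    keep <- e[, 1L] %in% ids & e[, 2L] %in% ids
    e <- e[keep, , drop = FALSE]
    if (nrow(e) == 0L) next
    i <- match(e[, 1L], ids); j <- match(e[, 2L], ids)
    x[cbind(i, j)] <- x[cbind(i, j)] + 1L
    x[cbind(j, i)] <- x[cbind(j, i)] + 1L
  }

  yab <- joint - x
  ya <- outer(seen_days, rep(1, n)) - joint   # days only the row ind. seen
  yb <- t(ya)
  dimnames(yab) <- dimnames(ya) <- dimnames(yb) <- dimnames(joint) <-
    list(ids, ids)
  denom <- x + yab + (ya + yb) / 2
  hwi <- ifelse(denom > 0, x / denom, 0)
  diag(hwi) <- 0
  # dyads never jointly sampled can never have a positive index
  structural <- joint == 0
  diag(structural) <- TRUE
  dimnames(hwi) <- list(ids, ids)
  structure(
    list(hwi = hwi, x = x, yab = yab, ya = ya, yb = yb, joint = joint,
         structural_zero = structural, ids = ids,
         criterion = assoc$criterion, threshold = assoc$threshold),
    class = "hwi_matrix"
  )
}

#' @export
print.hwi_matrix <- function(x, ...) {
  ut <- upper.tri(x$hwi)
  cat(sprintf(
    "Half-weight index matrix: %d individuals, mean HWI %.3f (%.1f%% zero)\n",
    length(x$ids), mean(x$hwi[ut]), 100 * mean(x$hwi[ut] == 0)))
  invisible(x)
}

#' @export
as.matrix.hwi_matrix <- function(x, ...) x$hwi
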