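# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain double loops and textbook formulas.

# O(N^2) pair enumerator for the lagged identification rate: for every
# unordered pair of records in the same event with 0 < lag <= max_lag,
# tally totals and same-individual counts per (ceiling) lag bin.
brute_lir <- function(records, max_lag = NULL) {
  if (is.null(max_lag)) {
    spread <- tapply(records$ordinal, records$event,
                     function(o) max(o) - min(o))
    max_lag <- max(spread)
  }
  nb <- as.integer(ceiling(max_lag))
  n_tau <- integer(nb)
  m_tau <- integer(nb)
  nr <- nrow(records)
  for (i in seq_len(nr - 1L)) {
    for (j in (i + 1L):nr) {
      if (records$event[i] != records$event[j]) next
      lag <- abs(records$ordinal[i] - records$ordinal[j])
      if (lag <= 0 || lag > max_lag) next
      bin <- as.integer(ceiling(lag))
      n_tau[bin] <- n_tau[bin] + 1L
      if (records$individual[i] == records$individual[j])
        m_tau[bin] <- m_tau[bin] + 1L
    }
  }
  data.frame(lag = seq_len(nb), m = m_tau, n = n_tau)[n_tau > 0, ]
}

# per-dyad half-weight tallies by direct day-by-day enumeration
brute_hwi <- function(assoc, ids) {
  ids <- sort(ids)
  n <- length(ids)
  h <- matrix(0, n, n, dimnames = list(ids, ids))
  for (ai in seq_len(n - 1L)) {
    for (bi in (ai + 1L):n) {
      a <- ids[ai]; b <- ids[bi]
      x <- yab <- ya <- yb <- 0
      for (k in seq_along(assoc$days)) {
        sa <- a %in% assoc$seen[[k]]
        sb <- b %in% assoc$seen[[k]]
        e <- assoc$edges[[k]]
        together <- nrow(e) > 0 &&
          any((e[, 1] == a & e[, 2] == b) | (e[, 1] == b & e[, 2] == a))
        if (together) x <- x + 1
        else if (sa && sb) yab <- yab + 1
        else if (sa) ya <- ya + 1
        else if (sb) yb <- yb + 1
      }
      den <- x + yab + (ya + yb) / 2
      if (den > 0) h[ai, bi] <- h[bi, ai] <- x / den
    }
  }
  h
}

# modularity from the e_kk / a_k formulation: Q = sum_k (e_kk - a_k^2),
# e_kk the fraction of edge weight inside cluster k, a_k the fraction of
# weight ending in cluster k
direct_q <- function(w, assignment) {
  tot <- sum(w)
  if (tot == 0) return(0)
  labs <- unique(assignment)
  q <- 0
  for (k in labs) {
    idx <- assignment == k
    e_kk <- sum(w[idx, idx]) / tot
    a_k <- sum(w[idx, ]) / tot
    q <- q + e_kk - a_k^2
  }
  q
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# random identification dataset with integer ordinals across a few events
random_records <- function(n_records, n_individuals = 8L, n_events = 4L,
                           ordinal_range = 120L) {
  ev <- sort(sample.int(n_events, n_records, replace = TRUE))
  data.frame(
    individual = sample(LETTERS[seq_len(n_individuals)], n_records,
                        replace = TRUE),
    event = sprintf("e%d", ev),
    ordinal = as.numeric(sample.int(ordinal_range, n_records,
                                    replace = TRUE)),
    date = as.Date("2005-06-01") + ev,
    stringsAsFactors = FALSE)
}

# compact simulated society reused by several test files
strong_signal_config <- function() {
  simulation_config(
    n_individuals = 20, n_units = 4, mean_residence = 40,
    mean_absence = 30, within_unit_cohesion = 1, between_unit_mixing = 0,
    frames_per_event = 15, events_per_day = 4, n_days = 20, n_years = 1,
    p_identify = 0.4)
}

unit_membership <- function(records) {
  first <- !duplicated(records$individual)
  stats::setNames(records$unit[first], records$individual[first])
}
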