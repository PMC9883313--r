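#' Coefficient of variation of association index values
#'
#' CV (population convention, standard deviation with denominator `n`) of
#' the off-diagonal half-weight indices, a standard summary of how mixed
#' strong and weak relationships are in a society: low values indicate
#' homogeneous association strengths, high values a blend of strong and
#' weak bonds. Because large numbers of never-associated dyads inflate the
#' CV, the non-zero variant restricts to dyads with a positive index
#' (structural zeros — dyads never jointly sampled — are thereby excluded
#' by definition).
#'
#' @param hwi an `"hwi_matrix"` or a symmetric numeric matrix.
#' @param nonzero_only if `TRUE`, compute the CV over non-zero indices only.
#' @return a single non-negative number.
#' @export
association_cv <- function(hwi, nonzero_only = FALSE) {
  m <- if (inherits(hwi, "hwi_matrix")) hwi$hwi else as.matrix(hwi)
  v <- m[upper.tri(m)]
  if (nonzero_only) v <- v[v > 0]
  if (length(v) < 2L)
    stop("need at least two dyads to compute a CV", call. = FALSE)
  mu <- mean(v)
  if (mu == 0)
    stop("mean association is zero; CV undefined", call. = FALSE)
  sqrt(mean((v - mu)^2)) / mu
}

# upper-triangle HWI values from tallies (x over fixed denominators)
hwi_values_from_x <- function(x, denom_ut, ut_idx) {
  v <- numeric(length(ut_idx))
  ok <- denom_ut > 0
  v[ok] <- x[ut_idx][ok] / denom_ut[ok]
  v
}

cv_pop <- function(v) {
  mu <- mean(v)
  if (mu == 0) return(NA_real_)
  sqrt(mean((v - mu)^2)) / mu
}

#' Permutation test of association CV within sampling days
#'
#' Tests whether the observed variation in association indices exceeds what
#' chance co-occurrence would produce, by randomizing *within* sampling
#' periods: each permutation applies `n_trials` attempted checkerboard flips
#' to randomly chosen days. A flip picks two associated dyads (i~j) and
#' (k~l) of one day with (i~l) and (k~j) not associated that day, and swaps
#' them — inverting a 2x2 part of that day's association matrix while
#' preserving every individual's number of associates that day and every
#' day's identification record. Flips accumulate across permutations
#' (sequential chain); after each permutation the half-weight matrix is
#' rebuilt from the permuted day-associations (identification histories, and
#' hence all HWI denominators, are unchanged) and the statistic recomputed.
#' The P value is one-sided high with add-one correction:
#' `P = (1 + #permuted >= observed) / (1 + n_permutations)`.
#'
#' @param assoc an `"association_data"` object.
#' @param n_permutations number of recorded permutations (default 1000).
#' @param n_trials attempted flips per permutation (default 1000).
#' @param statistic `"cv_all"` or `"cv_nonzero"` — the CV variant of
#'   [association_cv()] used as test statistic.
#' @param ids optional ID restriction passed to [hwi_matrix()].
#' @param seed optional seed (local to this call).
#' @param check_degrees if `TRUE`, assert after every flip that each
#'   individual's per-day association degree is unchanged (slow; for tests).
#' @return an object of class `"cv_permutation_test"`: list with `observed`,
#'   `null` (statistic after each permutation), `p_value`, `statistic`,
#'   `n_permutations`, `n_trials`, `n_flips` (accepted flips),
#'   `n_skipped_days` (trials that hit a day with fewer than two associated
#'   dyads), and `final_edges` (per-day dyad matrices after permutation).
#' @export
permute_within_days <- function(assoc, n_permutations = 1000L,
                                n_trials = 1000L,
                                statistic = c("cv_all", "cv_nonzero"),
                                ids = NULL, seed = NULL,
                                check_degrees = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(assoc, "association_data"))
  hw <- hwi_matrix(assoc, ids = ids)
  ids <- hw$ids
  n <- length(ids)
  denom <- hw$x + hw$yab + (hw$ya + hw$yb) / 2
  ut_idx <- which(upper.tri(denom))
  denom_ut <- denom[ut_idx]

  # per-day integer edge lists and adjacency, restricted to ids
  n_days <- length(assoc$days)
  edges <- vector("list", n_days)
  adj <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    e <- assoc$edges[[d]]
    keep <- e[, 1L] %in% ids & e[, 2L] %in% ids
    e <- e[keep, , drop = FALSE]
    ei <- cbind(match(e[, 1L], ids), match(e[, 2L], ids))
    edges[[d]] <- ei
    a <- matrix(FALSE, n, n)
    if (nrow(ei) > 0L) {
      a[ei] <- TRUE
      a[ei[, c(2L, 1L)]] <- TRUE
    }
    adj[[d]] <- a
  }
  x <- hw$x

  stat_fun <- function(x) {
    v <- hwi_values_from_x(x, denom_ut, ut_idx)
    if (statistic == "cv_nonzero") v <- v[v > 0]
    if (length(v) < 2L) return(NA_real_)
    cv_pop(v)
  }
  observed <- stat_fun(x)
  if (!is.finite(observed))
    stop("observed statistic is undefined on this dataset", call. = FALSE)

  runner <- function() {
    null_stats <- numeric(n_permutations)
    n_flips <- 0L
    n_skipped <- 0L
    edge_n <- vapply(edges, nrow, integer(1))
    for (p in seq_len(n_permutations)) {
      day_seq <- sample.int(n_days, n_trials, replace = TRUE)
      u1 <- stats::runif(n_trials)
      u2 <- stats::runif(n_trials)
      flip_or <- stats::runif(n_trials) < 0.5
      for (t in seq_len(n_trials)) {
        d <- day_seq[t]
        ne <- edge_n[d]
        if (ne < 2L) { n_skipped <- n_skipped + 1L; next }
        e1 <- 1L + as.integer(u1[t] * ne)
        e2 <- 1L + as.integer(u2[t] * (ne - 1L))
        if (e2 >= e1) e2 <- e2 + 1L
        E <- edges[[d]]
        i <- E[e1, 1L]; j <- E[e1, 2L]
        k <- E[e2, 1L]; l <- E[e2, 2L]
        if (flip_or[t]) { tmp <- k; k <- l; l <- tmp }
        # candidate new edges (i,l) and (k,j)
        if (i == l || k == j || i == k || j == l) next
        A <- adj[[d]]
        if (A[i, l] || A[k, j]) next
        # apply the checkerboard swap
        A[i, j] <- A[j, i] <- FALSE
        A[k, l] <- A[l, k] <- FALSE
        A[i, l] <- A[l, i] <- TRUE
        A[k, j] <- A[j, k] <- TRUE
        adj[[d]] <<- A
        edges[[d]][e1, ] <<- c(i, l)
        edges[[d]][e2, ] <<- c(k, j)
        x[i, j] <<- x[i, j] - 1L; x[j, i] <<- x[j, i] - 1L
        x[k, l] <<- x[k, l] - 1L; x[l, k] <<- x[l, k] - 1L
        x[i, l] <<- x[i, l] + 1L; x[l, i] <<- x[l, i] + 1L
        x[k, j] <<- x[k, j] + 1L; x[j, k] <<- x[j, k] + 1L
        n_flips <- n_flips + 1L
        if (check_degrees) {
          deg <- rowSums(A)
          stopifnot(identical(deg, .pd_deg0[[d]]))
        }
      }
      null_stats[p] <- stat_fun(x)
    }
    list(null = null_stats, n_flips = n_flips, n_skipped = n_skipped)
  }

  if (check_degrees) .pd_deg0 <- lapply(adj, rowSums)

  res <- if (is.null(seed)) runner() else with_local_seed(seed, runner())
  null_stats <- res$null
  p_value <- (1 + sum(null_stats >= observed, na.rm = TRUE)) /
    (1 + n_permutations)

  structure(
    list(observed = observed, null = null_stats, p_value = p_value,
         statistic = statistic,
         n_permutations = n_permutations, n_trials = n_trials,
         n_flips = res$n_flips, n_skipped_days = res$n_skipped,
         final_edges = edges, ids = ids),
    class = "cv_permutation_test"
  )
}

#' @export
print.cv_permutation_test <- function(x, ...) {
  cat(sprintf(
    "Within-day permutation test of %s\n  observed %.4f, null mean %.4f, P = %.4g (%d permutations x %d trials, %d flips)\n",
    x$statistic, x$observed, mean(x$null, na.rm = TRUE), x$p_value,
    x$n_permutations, x$n_trials, x$n_flips))
  invisible(x)
}

#' Mantel test of association strength against group membership
#'
#' Pearson correlation between the off-diagonal half-weight indices and a
#' binary same-group indicator matrix (1 when two individuals share a group
#' label, e.g. the same matriline), with significance from simultaneously
#' permuting individuals' labels — i.e. permuting rows and columns of the
#' indicator matrix together. One-sided for positive correlation (stronger
#' associations within groups), with add-one correction.
#'
#' @param hwi an `"hwi_matrix"` or symmetric numeric matrix with dimnames.
#' @param membership named vector (or factor) of group labels, names
#'   covering every individual in `hwi`.
#' @param n_permutations number of label permutations (default 1000).
#' @param seed optional seed (local to this call).
#' @return an object of class `"mantel_result"`: list with
#'   `matrix_correlation`, `p_value`, `null` and `n_permutations`.
#' @export
mantel_association_test <- function(hwi, membership,
                                    n_permutations = 1000L, seed = NULL) {
  m <- if (inherits(hwi, "hwi_matrix")) hwi$hwi else as.matrix(hwi)
  ids <- rownames(m)
  if (is.null(ids)) stop("`hwi` must carry individual IDs as dimnames",
                         call. = FALSE)
  if (is.null(names(membership)))
    stop("`membership` must be named by individual ID", call. = FALSE)
  if (!all(ids %in% names(membership)))
    stop("membership labels missing for some individuals", call. = FALSE)
  g <- as.character(membership[ids])
  if (length(unique(g)) < 2L)
    stop("membership has a single group; indicator matrix is degenerate",
         call. = FALSE)
  if (length(unique(g)) == length(g))
    stop("every individual is its own group; indicator matrix is degenerate",
         call. = FALSE)
  same <- outer(g, g, "==") * 1
  ut <- upper.tri(m)
  r_obs <- stats::cor(m[ut], same[ut])

  runner <- function() {
    vapply(seq_len(n_permutations), function(p) {
      pg <- g[sample.int(length(g))]
      stats::cor(m[ut], (outer(pg, pg, "==") * 1)[ut])
    }, numeric(1))
  }
  null_r <- if (is.null(seed)) runner() else with_local_seed(seed, runner())
  p_value <- (1 + sum(null_r >= r_obs)) / (1 + n_permutations)
  structure(
    list(matrix_correlation = r_obs, p_value = p_value, null = null_r,
         n_permutations = n_permutations),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "Mantel test: matrix correlation %.3f, P = %.4g (%d permutations)\n",
    x$matrix_correlation, x$p_value, x$n_permutations))
  invisible(x)
}

# modularity of a partition of a weighted graph:
# Q = (1/2W) * sum_ij (w_ij - s_i s_j / 2W) delta(c_i, c_j)
modularity_q <- function(w, assignment) {
  tot <- sum(w)
  if (tot == 0) return(0)
  s <- rowSums(w)
  same <- outer(assignment, assignment, "==")
  sum((w - outer(s, s) / tot) * same) / tot
}

#' Community detection by leading-eigenvector modularity maximization
#'
#' Recursive spectral bisection of a weighted association network: at each
#' step the group's generalized modularity matrix
#' `B_ij = w_ij - s_i s_j / (2W)` (degree-corrected within the group) is
#' split by the sign of its leading eigenvector, and the split is accepted
#' only if it increases modularity `Q`. No fine-tuning pass is applied.
#'
#' @param hwi an `"hwi_matrix"` or a symmetric non-negative weight matrix.
#' @param tol numeric tolerance for a positive eigenvalue / modularity gain.
#' @return an object of class `"community_partition"`: list with
#'   `assignment` (named integer cluster labels), `q` (modularity,
#'   recomputed directly from the returned assignment), `n_clusters` and
#'   `cluster_sizes`.
#' @export
newman_communities <- function(hwi, tol = 1e-10) {
  w <- if (inherits(hwi, "hwi_matrix")) hwi$hwi else as.matrix(hwi)
  n <- nrow(w)
  if (n == 0L) stop("empty association matrix", call. = FALSE)
  if (!isSymmetric(unname(w), tol = 1e-8))
    stop("association matrix must be symmetric", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  diag(w) <- 0
  ids <- rownames(w)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  tot <- sum(w)                       # = 2W
  assignment <- rep(1L, n)
  if (tot > 0) {
    s <- rowSums(w)
    B <- w - outer(s, s) / tot
    next_label <- 2L
    stack <- list(seq_len(n))
    while (length(stack) > 0L) {
      g <- stack[[1L]]; stack <- stack[-1L]
      if (length(g) < 2L) next
      Bg <- B[g, g, drop = FALSE]
      diag(Bg) <- diag(Bg) - rowSums(Bg)
      eig <- eigen(Bg, symmetric = TRUE)
      if (eig$values[1L] <= tol) next
      sv <- ifelse(eig$vectors[, 1L] >= 0, 1, -1)
      if (all(sv == sv[1L])) next
      dq <- as.numeric(t(sv) %*% Bg %*% sv) / (2 * tot)
      if (dq <= tol) next
      part2 <- g[sv < 0]
      assignment[part2] <- next_label
      next_label <- next_label + 1L
      stack <- c(stack, list(g[sv > 0]), list(part2))
    }
  }
  # relabel clusters consecutively in order of appearance
  assignment <- match(assignment, unique(assignment))
  names(assignment) <- ids
  q <- modularity_q(w, assignment)
  sizes <- as.integer(table(assignment))
  structure(
    list(assignment = assignment, q = q,
         n_clusters = length(sizes), cluster_sizes = sizes),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf(
    "Community partition: %d clusters (sizes %s), Q = %.3f\n",
    x$n_clusters, paste(x$cluster_sizes, collapse = ", "), x$q))
  invisible(x)
}

#' Maximum-likelihood beta-binomial fit to dyadic tallies
#'
#' Fits the latent-association model in which each dyad's true association
#' probability is drawn from a Beta(`alpha`, `beta`) distribution and the
#' observed count of associated days is Binomial given that probability, so
#' the counts are marginally beta-binomial. Maximized by Nelder--Mead on
#' `(log alpha, log beta)` from a 4x4 grid of starts.
#'
#' @param x integer vector: days each dyad was associated.
#' @param d integer vector: days each dyad was jointly sampled (`x <= d`);
#'   dyads with `d = 0` are dropped.
#' @return list with `alpha`, `beta`, `loglik`, `boundary` (TRUE when the
#'   optimum ran to the homogeneous limit `alpha + beta -> Inf`),
#'   `start_logliks` and `n_dyads`.
#' @export
fit_beta_binomial <- function(x, d) {
  keep <- d > 0
  x <- x[keep]; d <- d[keep]
  if (length(x) == 0L)
    stop("no dyads with positive joint sampling", call. = FALSE)
  if (any(x < 0) || any(x > d))
    stop("need 0 <= x <= d for every dyad", call. = FALSE)
  const <- sum(lchoose(d, x))
  ll <- function(lp) {
    a <- exp(lp[1L]); b <- exp(lp[2L])
    if (!is.finite(a) || !is.finite(b)) return(-1e12)
    const + sum(lbeta(x + a, d - x + b) - lbeta(a, b))
  }
  grid <- as.matrix(expand.grid(la = c(-2, -0.5, 1, 2.5),
                                lb = c(-2, -0.5, 1, 2.5)))
  start_ll <- apply(grid, 1L, ll)
  best <- NULL
  for (i in order(start_ll, decreasing = TRUE)[1:4]) {
    o <- stats::optim(grid[i, ], function(p) -ll(p),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  alpha <- exp(best$par[1L]); beta <- exp(best$par[2L])
  boundary <- (alpha + beta) > 1e5
  list(alpha = alpha, beta = beta, loglik = -best$value,
       boundary = boundary, start_logliks = start_ll,
       n_dyads = length(x))
}

#' Social differentiation by the likelihood method
#'
#' Estimates `S`, the coefficient of variation of the dyads' *true* (latent)
#' association probabilities, corrected for binomial sampling noise, via the
#' beta-binomial model of [fit_beta_binomial()]:
#' \deqn{S = \sqrt{\beta / (\alpha(\alpha+\beta+1))},}
#' the CV of a Beta(`alpha`, `beta`) distribution. Values near 0 indicate
#' homogeneous associations; values above 1 indicate highly diverse
#' relationships across dyads.
#'
#' @param assoc an `"association_data"` object (tallies are derived with
#'   [hwi_matrix()]), or `NULL` if `x` and `d` are supplied directly.
#' @param ids optional ID restriction.
#' @param x,d optional per-dyad tallies (associated days, jointly sampled
#'   days) overriding `assoc`.
#' @return an object of class `"social_differentiation"`: list with `s`,
#'   `alpha`, `beta`, `loglik`, `boundary`, `n_dyads` and `start_logliks`.
#'   At a boundary (homogeneous) fit `s` is 0 and `boundary` is `TRUE`.
#' @export
social_differentiation <- function(assoc = NULL, ids = NULL,
                                   x = NULL, d = NULL) {
  if (is.null(x) || is.null(d)) {
    stopifnot(inherits(assoc, "association_data"))
    hw <- hwi_matrix(assoc, ids = ids)
    ut <- upper.tri(hw$x)
    x <- hw$x[ut]
    d <- hw$joint[ut]
  }
  fit <- fit_beta_binomial(x, d)
  s <- if (fit$boundary) 0 else
    sqrt(fit$beta / (fit$alpha * (fit$alpha + fit$beta + 1)))
  structure(c(list(s = s), fit), class = "social_differentiation")
}

#' @export
print.social_differentiation <- function(x, ...) {
  cat(sprintf(
    "Social differentiation S = %.3f (beta-binomial alpha %.3g, beta %.3g%s, %d dyads)\n",
    x$s, x$alpha, x$beta, if (x$boundary) ", boundary fit" else "",
    x$n_dyads))
  invisible(x)
}
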