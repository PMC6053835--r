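# Enumerate all assignments of N pooled observations to groups of the
# given sizes; returns a list of integer index vectors per group.
# Used only for exact small-sample p-values.
enum_group_assignments <- function(N, sizes) {
  if (length(sizes) == 1) {
    stopifnot(sizes == N)
    return(list(list(seq_len(N))))
  }
  first <- utils::combn(N, sizes[1], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest_idx <- setdiff(seq_len(N), f)
    for (tail in enum_group_assignments(length(rest_idx), sizes[-1])) {
      out[[length(out) + 1L]] <- c(list(f), lapply(tail, function(ix) rest_idx[ix]))
    }
  }
  out
}

mw_u <- function(ranks, idx1, n1, n2) {
  sum(ranks[idx1]) - n1 * (n1 + 1) / 2
}

kw_h <- function(ranks, idx_groups, N, tie_correction) {
  s <- sum(vapply(idx_groups,
                  function(ix) sum(ranks[ix])^2 / length(ix), numeric(1)))
  h <- 12 / (N * (N + 1)) * s - 3 * (N + 1)
  h / tie_correction
}

#' Rank-based group contrast
#'
#' Compares per-patient values (mutational burden, shared fraction, ...)
#' across clinical groups with the rank tests used throughout the
#' analysis: Mann-Whitney U for two groups, Kruskal-Wallis for two or
#' more. For small layouts (combined n at most `exact_max`, default 12)
#' the two-sided p-value is computed by exhaustive enumeration of all
#' group assignments of the pooled mid-ranks, which is valid under ties;
#' larger layouts use the tie-corrected normal (Mann-Whitney, with
#' continuity correction via [stats::wilcox.test()]) or chi-square
#' (Kruskal-Wallis, via [stats::kruskal.test()]) approximation.
#'
#' For the Mann-Whitney enumeration the two-sided p-value is the null
#' probability of a U statistic at least as extreme (in either direction)
#' as observed: `P(min(U, n1*n2 - U) <= min(u_obs, n1*n2 - u_obs))`.
#'
#' @param groups List of two (Mann-Whitney) or more (Kruskal-Wallis)
#'   numeric vectors, each non-empty.
#' @param kind `"mann_whitney"` or `"kruskal_wallis"`.
#' @param exact_max Largest combined sample size for which exact
#'   enumeration is used (enumeration is additionally capped at 1e5
#'   assignments for many-group layouts).
#' @return List with `statistic` (U for group 1, or H), `p_value`,
#'   `method`, and `exact` (logical).
#' @export
#' @examples
#' contrast(list(c(1, 2, 3, 4), c(10, 11, 12, 13)), "mann_whitney")
contrast <- function(groups, kind = c("mann_whitney", "kruskal_wallis"),
                     exact_max = 12) {
  kind <- match.arg(kind)
  if (!is.list(groups) || length(groups) < 2)
    stop("'groups' must be a list of at least two numeric vectors")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must contain at least one observation")
  if (kind == "mann_whitney" && length(groups) != 2)
    stop("mann_whitney requires exactly two groups")

  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  ranks <- rank(pooled)
  idx_groups <- split(seq_len(N), rep(seq_along(groups), sizes))
  ties <- table(pooled)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)

  n_assignments <- prod(choose(rev(cumsum(rev(sizes))), sizes))
  do_exact <- N <= exact_max && n_assignments <= 1e5

  if (kind == "mann_whitney") {
    n1 <- sizes[1]; n2 <- sizes[2]
    u_obs <- mw_u(ranks, idx_groups[[1]], n1, n2)
    if (do_exact) {
      assignments <- utils::combn(N, n1, simplify = FALSE)
      u_all <- vapply(assignments, function(ix) mw_u(ranks, ix, n1, n2),
                      numeric(1))
      extremity <- pmin(u_all, n1 * n2 - u_all)
      p <- mean(extremity <= min(u_obs, n1 * n2 - u_obs) + 1e-9)
      return(list(statistic = u_obs, p_value = p,
                  method = "Mann-Whitney U (exact enumeration)", exact = TRUE))
    }
    wt <- stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE,
                             correct = TRUE)
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                method = "Mann-Whitney U (normal approximation)",
                exact = FALSE))
  }

  # Kruskal-Wallis
  if (tie_corr <= 0) stop("all observations identical; contrast undefined")
  h_obs <- kw_h(ranks, idx_groups, N, tie_corr)
  if (do_exact) {
    assignments <- enum_group_assignments(N, sizes)
    h_all <- vapply(assignments,
                    function(gs) kw_h(ranks, gs, N, tie_corr), numeric(1))
    p <- mean(h_all >= h_obs - 1e-9)
    return(list(statistic = h_obs, p_value = p,
                method = "Kruskal-Wallis (exact enumeration)", exact = TRUE))
  }
  kt <- stats::kruskal.test(pooled, factor(rep(seq_along(groups), sizes)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       method = "Kruskal-Wallis (chi-square approximation)", exact = FALSE)
}
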