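# The statistical battery: Yates-corrected chi-square, Wilcoxon rank sum
# with an exact tie-aware permutation distribution, Rayleigh uniformity
# test, and the Mardia-Watson-Wheeler uniform-scores test with repeated
# random tie breaking.

new_test_result <- function(method, statistic, p, df = NA_integer_,
                            n = integer(0), extras = list()) {
  stopifnot(is.finite(statistic), p >= 0, p <= 1 + 1e-12)
  structure(list(method = method, statistic = statistic, df = df,
                 p = min(p, 1), n = n, extras = extras),
            class = "trait_test")
}

#' @export
print.trait_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g%s, p = %.3f",
              x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %d", x$df), x$p))
  if (length(x$n)) cat(sprintf("  (n = %s)", paste(x$n, collapse = "/")))
  cat("\n")
  ex <- x$extras[vapply(x$extras, function(e) is.numeric(e) && length(e) == 1,
                        logical(1))]
  if (length(ex))
    cat("  ", paste(sprintf("%s = %.4g", names(ex), unlist(ex)),
                    collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pearson chi-square test with continuity correction on a 2x2 table
#'
#' Computes \code{sum(max(|O - E| - 0.5, 0)^2 / E)} on the table
#' \code{rbind(c(a, b), c(c, d))} with expectations from the margins, and the
#' p-value from the upper tail of the chi-square distribution with 1 df. The
#' correction is truncated at zero, so a perfectly balanced table gives a
#' statistic of exactly 0 and p = 1.
#'
#' @param a,b Counts in the first group (e.g. departed / stayed).
#' @param c,d Counts in the second group.
#' @return A \code{trait_test} with statistic, df = 1 and p.
#' @export
#' @examples
#' chi2_yates_2x2(39, 24, 32, 29)  # chi2 = 0.777, p = 0.378
chi2_yates_2x2 <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  if (any(!is.finite(o)) || any(o < 0))
    stop("invalid-input: counts must be non-negative", call. = FALSE)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("degenerate-table error: a margin of the 2x2 table is zero",
         call. = FALSE)
  n <- sum(o)
  e <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / n
  stat <- sum(pmax(abs(o - e) - 0.5, 0)^2 / e)
  new_test_result("Pearson chi-square with continuity correction",
                  stat, stats::pchisq(stat, 1, lower.tail = FALSE), df = 1L,
                  n = c(a + b, c + d))
}

# Exact permutation distribution of the scaled (x2, integer) midrank sum:
# two-sided tail probability P(|T - E T| >= |t_obs - E T|), enumerated over
# the smaller group by the compiled dynamic programme.
exact_ranksum_p <- function(ranks2, nx, sum_x2) {
  N <- length(ranks2)
  m <- min(nx, N - nx)
  if (m != nx) sum_x2 <- sum(ranks2) - sum_x2   # work with the smaller group
  exact_ranksum_p_cpp(ranks2, m, sum_x2)
}

#' Wilcoxon rank sum test with exact tie-aware p-values
#'
#' Two-sided two-sample rank test. The statistic is
#' \code{W = sum(rank(x)) - nx (nx + 1) / 2} (the Mann-Whitney count, as
#' printed by R). Exact p-values are obtained from the full permutation
#' distribution of the midrank sum, computed by a count-generating dynamic
#' programme over the observed pooled values -- ties therefore pose no
#' obstacle to exactness. The normal approximation uses the tie-corrected
#' variance and a 0.5 continuity correction.
#'
#' Policy \code{"auto"} uses the exact distribution when the pooled sample
#' size is at most 30, or when ties are present and the pooled size is at
#' most \code{exact_cap}; beyond that the tie-corrected normal approximation
#' takes over (the exact enumeration's cost grows with the square of the
#' sample size times the rank-sum range).
#'
#' @param x,y Numeric samples, both non-empty.
#' @param policy \code{"auto"}, \code{"exact"} or \code{"normal"}.
#' @param exact_cap Largest pooled size for which \code{"auto"} stays exact
#'   in the presence of ties.
#' @return A \code{trait_test}; \code{extras$exact} records which route ran.
#' @export
#' @examples
#' wilcoxon_ranksum(c(1, 2), c(3, 4))$p  # 1/3 by enumeration of all 6 splits
wilcoxon_ranksum <- function(x, y, policy = c("auto", "exact", "normal"),
                             exact_cap = 100) {
  policy <- match.arg(policy)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("invalid-input: both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  exact <- switch(policy,
                  exact = TRUE, normal = FALSE,
                  auto = N <= 30 || (ties && N <= exact_cap))
  if (exact) {
    ranks2 <- as.integer(round(2 * rk))   # midranks doubled are integers
    p <- exact_ranksum_p(ranks2, nx, sum(ranks2[seq_len(nx)]))
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    sigma2 <- nx * ny / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1    # all observations identical
    } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  new_test_result(
    paste0("Wilcoxon rank sum test (",
           if (exact) "exact permutation" else "normal approximation", ")"),
    W, p, n = c(nx, ny), extras = list(exact = exact, ties = ties))
}

#' Rayleigh test of circular uniformity
#'
#' Computes the mean resultant length \code{r = |sum(exp(i theta))| / n} and
#' tests uniformity with the standard series approximation
#' \code{p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))} with
#' \code{R = n r}.
#'
#' @param angles_deg Angles in degrees (any reference direction), n >= 2.
#' @return A \code{trait_test}; the statistic is \code{Z = n r^2} and
#'   \code{extras} carry \code{r} and the mean direction in degrees.
#' @export
#' @examples
#' rayleigh_test(c(80, 90, 100))$extras$r
rayleigh_test <- function(angles_deg) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  n <- length(angles_deg)
  if (n < 2) stop("invalid-input: need at least 2 angles", call. = FALSE)
  th <- angles_deg * pi / 180
  C <- sum(cos(th)); S <- sum(sin(th))
  R <- sqrt(C^2 + S^2)
  r <- R / n
  Z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  mean_dir <- (atan2(S, C) * 180 / pi) %% 360
  new_test_result("Rayleigh test of uniformity", Z,
                  max(0, min(1, p)), n = n,
                  extras = list(r = r, mean_direction = mean_dir))
}

# One uniform-scores evaluation on a given tie-broken ranking.
mww_w_from_ranks <- function(rk, n1, n2) {
  N <- n1 + n2
  beta <- 2 * pi * rk / N
  C1 <- sum(cos(beta[seq_len(n1)])); S1 <- sum(sin(beta[seq_len(n1)]))
  C2 <- sum(cos(beta[n1 + seq_len(n2)])); S2 <- sum(sin(beta[n1 + seq_len(n2)]))
  2 * ((C1^2 + S1^2) / n1 + (C2^2 + S2^2) / n2)
}

#' Mardia-Watson-Wheeler (uniform scores) two-sample test
#'
#' Tests whether two samples of angles differ in mean direction, angular
#' variance or both. Pooled circular ranks are mapped to uniform scores
#' \code{beta_j = 2 pi rank_j / N}; the statistic is
#' \code{W = 2 [ (C1^2 + S1^2)/n1 + (C2^2 + S2^2)/n2 ]} with \code{C_g, S_g}
#' the cosine/sine sums of group g's scores, referred to a chi-square
#' distribution with 2 df.
#'
#' Ranks are undefined under ties, so when tied angles are present the tied
#' observations are randomly ordered, the test is repeated \code{reps} times
#' (seeded), and the medians of the statistic and p-value over the
#' repetitions are reported. Tie-free data are evaluated once.
#'
#' An exact reference is available with \code{p_method = "permutation"}:
#' within each (tie-broken) evaluation, the p-value is the fraction of
#' \code{n_perm} random group relabelings with W at least as large as
#' observed. The chi-square approximation is crude below ~10 angles per
#' group, hence the warning.
#'
#' @param angles1_deg,angles2_deg Angle samples in degrees, >= 4 each.
#' @param seed Integer seed for tie breaking (and permutation draws).
#' @param reps Tie-breaking repetitions (>= 1); ignored for tie-free data.
#' @param p_method \code{"chisq"} (default) or \code{"permutation"}.
#' @param n_perm Relabelings per evaluation for the permutation p.
#' @return A \code{trait_test}; \code{extras} record the number of
#'   repetitions actually run and whether ties were present.
#' @export
#' @examples
#' set.seed(1)
#' mww_test(runif(12, 0, 90), runif(12, 180, 270), seed = 1)$p
mww_test <- function(angles1_deg, angles2_deg, seed = NULL, reps = 10000,
                     p_method = c("chisq", "permutation"), n_perm = 2000) {
  p_method <- match.arg(p_method)
  a1 <- angles1_deg[!is.na(angles1_deg)] %% 360
  a2 <- angles2_deg[!is.na(angles2_deg)] %% 360
  n1 <- length(a1); n2 <- length(a2); N <- n1 + n2
  if (n1 < 4 || n2 < 4)
    stop("sample-size error: need at least 4 angles per group", call. = FALSE)
  if (n1 < 10 || n2 < 10)
    warning("fewer than 10 angles in a group: the chi-square approximation ",
            "is crude at this size", call. = FALSE)
  if (!is.finite(reps) || reps < 1)
    stop("invalid-input: reps must be >= 1", call. = FALSE)
  pooled <- c(a1, a2)
  ties <- anyDuplicated(pooled) > 0
  n_eval <- if (ties) as.integer(reps) else 1L
  if (!is.null(seed)) set.seed(as.integer(seed))
  rks <- vapply(seq_len(n_eval), function(j)
    rank(pooled, ties.method = if (ties) "random" else "average"),
    numeric(N))
  beta <- 2 * pi * rks / N
  cb <- cos(beta); sb <- sin(beta)
  i1 <- seq_len(n1)
  W_all <- 2 * ((colSums(cb[i1, , drop = FALSE])^2 +
                   colSums(sb[i1, , drop = FALSE])^2) / n1 +
                (colSums(cb[-i1, , drop = FALSE])^2 +
                   colSums(sb[-i1, , drop = FALSE])^2) / n2)
  p_all <- if (p_method == "chisq") {
    stats::pchisq(W_all, 2, lower.tail = FALSE)
  } else {
    vapply(seq_len(n_eval), function(j) {
      wperm <- replicate(n_perm,
                         mww_w_from_ranks(rks[sample.int(N), j], n1, n2))
      mean(wperm >= W_all[j] - 1e-12)
    }, numeric(1))
  }
  ev <- rbind(W_all, p_all)
  W_med <- stats::median(ev[1, ])
  p_med <- stats::median(ev[2, ])
  new_test_result(
    paste0("Mardia-Watson-Wheeler uniform-scores test",
           if (ties) sprintf(" (median of %d random tie-break runs)", n_eval)
           else "",
           if (p_method == "permutation") ", permutation p" else ""),
    W_med, p_med, df = if (p_method == "chisq") 2L else NA_integer_,
    n = c(n1, n2),
    extras = list(ties = ties, reps = n_eval,
                  w_spread = unname(stats::quantile(ev[1, ], c(0.25, 0.75)))))
}

#' Two-sample t-test on group means
#'
#' Pooled-variance by default (Welch switchable), two-sided. When both
#' groups are constant with equal means the comparison is vacuous and p = 1
#' is returned by convention; constant groups with different means are a
#' degenerate input.
#'
#' @param x,y Numeric samples, >= 2 each.
#' @param var_equal Pool the variances (default) or use Welch's correction.
#' @return A \code{trait_test}.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))$statistic  # -3.674
two_sample_t <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("invalid-input: need at least 2 observations per group",
         call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(new_test_result("Two-sample t-test (pooled variance)", 0, 1,
                             df = length(x) + length(y) - 2L,
                             n = c(length(x), length(y))))
    stop("degenerate-input error: both groups constant with unequal means",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  new_test_result(
    if (var_equal) "Two-sample t-test (pooled variance)"
    else "Welch two-sample t-test",
    unname(ht$statistic), ht$p.value, df = unname(ht$parameter),
    n = c(length(x), length(y)))
}
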