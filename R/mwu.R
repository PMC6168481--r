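# Mann-Whitney U comparison of two rank distributions.

# Midranks of the pooled sample.
.midranks <- function(x) rank(x, ties.method = "average")

#' Compare two rank distributions (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test on two samples of ranks (e.g. the ranks a
#' method assigns to causative variants across cases, versus a competing
#' method). `U` is reported for the first sample, counting pairs where its
#' value exceeds the other's plus half-ties. For small samples (at most 20
#' per group) the p-value is exact: via the null U distribution when there
#' are no ties, and by full enumeration of the permutation null (all
#' reassignments of the pooled values to the two groups) when ties are
#' present and the enumeration is tractable; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param ranks_a,ranks_b Nonempty numeric vectors.
#' @param exact_cap Largest number of group assignments that will be
#'   enumerated for the tied exact test (default 2e5).
#' @return List with `U`, `p` and `method` (a label for the p-value
#'   route).
#' @export
compare_rank_distributions <- function(ranks_a, ranks_b, exact_cap = 2e5) {
  a <- as.numeric(ranks_a); b <- as.numeric(ranks_b)
  if (!length(a) || !length(b)) {
    stop("both rank lists must be nonempty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  mr <- .midranks(pooled)
  U <- sum(mr[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  small <- n1 <= 20 && n2 <= 20

  if (small && !ties) {
    # exact null U distribution (no ties)
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        1 - stats::pwilcox(U - 1, n1, n2)))
    return(list(U = U, p = p, method = "exact"))
  }
  if (small && choose(N, n1) <= exact_cap) {
    # exact permutation null under the observed tie pattern
    subsets <- combn(N, n1)
    base <- n1 * (n1 + 1) / 2
    u_all <- colSums(matrix(mr[subsets], nrow = n1)) - base
    dev <- abs(u_all - n1 * n2 / 2)
    p <- mean(dev >= abs(U - n1 * n2 / 2) - 1e-9)
    return(list(U = U, p = p, method = "exact-permutation"))
  }
  # normal approximation with tie correction and continuity correction
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - corr)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}
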