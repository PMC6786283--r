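#' Normalize densitometry intensities against loading controls
#'
#' Each sample's target band intensity is divided by its loading-control
#' intensity (when two loading channels are given, e.g. beta-actin and
#' histone H3, their geometric mean is used), then scaled so the mean ratio
#' of the reference group maps to 1.
#'
#' @param samples data.frame with columns `group`, `replicate`, `target`,
#'   `loading1` and optionally `loading2` (all intensities > 0)
#' @param reference group label (or replicate id) defining the unit level
#' @return `samples` with a `normalized` column added
#' @export
normalize_densitometry <- function(samples, reference) {
  stopifnot(is.data.frame(samples),
            all(c("group", "replicate", "target", "loading1") %in% names(samples)))
  if (any(samples$loading1 <= 0) ||
      ("loading2" %in% names(samples) && any(samples$loading2 <= 0)))
    stop("loading intensities must be > 0")
  loading <- if ("loading2" %in% names(samples)) {
    sqrt(samples$loading1 * samples$loading2)
  } else {
    samples$loading1
  }
  ratio <- samples$target / loading
  ref <- samples$group == reference | samples$replicate == reference
  if (!any(ref)) stop("reference group/replicate not present")
  samples$normalized <- ratio / mean(ratio[ref])
  samples
}

# cache of exact U null distributions, keyed "n1,n2"
.u_dist_cache <- new.env(parent = emptyenv())

# exact null distribution of U by full enumeration of all C(n1+n2, n1)
# assignments of pooled ranks to group 1 (no ties assumed)
exact_u_distribution <- function(n1, n2) {
  key <- paste(n1, n2, sep = ",")
  hit <- .u_dist_cache[[key]]
  if (!is.null(hit)) return(hit)
  N <- n1 + n2
  combos <- utils::combn(N, n1)
  u <- colSums(matrix(seq_len(N)[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  tab <- tabulate(u + 1L, nbins = n1 * n2 + 1L)
  dist <- tab / ncol(combos)          # P(U = 0..n1*n2)
  .u_dist_cache[[key]] <- dist
  dist
}

#' Two-tailed Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. When
#' `min(n1, n2) <= 10` and the pooled data are tie-free, the two-sided p is
#' exact: the null distribution of U is obtained by full enumeration of all
#' `choose(n1+n2, n1)` group labelings, and `p = min(1, 2 min(P(U <= u),
#' P(U >= u)))`. Otherwise the normal approximation is used, with continuity
#' correction and the standard tie correction to the variance; at `U` equal
#' to its null mean the approximation reports p = 1.
#'
#' @param x,y numeric samples (non-empty)
#' @return an object of class `group_comparison` with `U` (for `x`),
#'   `p_two_sided`, `method` (`"exact"` or `"normal-approximation"`), `n1`,
#'   `n2`
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  stopifnot(is.numeric(x), is.numeric(y),
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)                   # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0

  if (!has_ties && min(n1, n2) <= 10) {
    dist <- exact_u_distribution(n1, n2)
    Ui <- as.integer(round(U))
    p_le <- sum(dist[seq_len(Ui + 1L)])
    p_ge <- sum(dist[seq(Ui + 1L, length(dist))])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      # continuity correction applied toward the mean, never past it
      z <- sign(U - mu) * max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-approximation"
  }
  structure(list(U = U, p_two_sided = p, method = method,
                 n1 = n1, n2 = n2, percent_change = NA_real_),
            class = "group_comparison")
}

#' Percent change between groups with a Mann-Whitney p-value
#'
#' Change of group b relative to group a as a percent of a's mean
#' (`100 (mean_b - mean_a) / mean_a`; a 1.0 to 0.7 shift is -30%), with the
#' two-sided p from [mann_whitney_u()].
#'
#' @param group_a reference-group normalized values
#' @param group_b comparison-group normalized values
#' @return a `group_comparison` with `percent_change` populated
#' @export
diurnal_change <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  m_a <- mean(group_a)
  if (m_a == 0) stop("reference group mean is zero")
  cmp <- mann_whitney_u(group_a, group_b)
  cmp$percent_change <- 100 * (mean(group_b) - m_a) / m_a
  cmp
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method))
  if (!is.na(x$percent_change))
    cat(sprintf("  percent change vs reference: %+.1f%%\n", x$percent_change))
  invisible(x)
}
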