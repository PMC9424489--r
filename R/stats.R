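#' Mann-Whitney U test (two-sided)
#'
#' Self-contained rank-sum test. U is computed from midranks (ties allowed).
#' When the pooled sample is small (n1 + n2 <= 12) and tie-free, the
#' two-sided p value is exact, by full enumeration of all choose(n1+n2, n1)
#' group assignments of the ranks (probability of a U at least as far from
#' the null mean n1*n2/2 as observed). Otherwise a normal approximation with
#' continuity correction and tie-corrected variance is used.
#'
#' @param a,b numeric samples, each non-empty
#' @return A \linkS4class{UTestResult}.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # exact two-sided p = 1/3
#' @export
mannWhitneyU <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("samples may not contain NA", call. = FALSE)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  rk <- rank(pooled) # midranks
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  mu <- n1 * n2 / 2
  if (!ties && N <= 12L) {
    picks <- combn(N, n1)
    us <- colSums(matrix(rk[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1 # all observations identical
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal_approx_tie_corrected"
  }
  new("UTestResult", uStatistic = u, n1 = as.integer(n1), n2 = as.integer(n2),
      pTwoSided = p, method = method)
}

#' Compare two groups of segment features
#'
#' Applies the Mann-Whitney U test to a chosen morphometric feature at a
#' chosen unit of analysis: \code{"segment"} pools individual segments
#' across volumes within each group, \code{"volume_mean"} first averages per
#' volume and compares the per-volume means (requiring at least two volumes
#' per group). No multiple-testing correction is applied across features.
#'
#' @param groupA,groupB feature tables from [extractFeatures()] (rows of all
#'   group members concatenated)
#' @param feature \code{"length_um"} or \code{"avg_cross_section_um2"}
#' @param unit \code{"segment"} (default) or \code{"volume_mean"}
#' @param alpha significance level for the flag (default 0.05)
#' @param labels character(2) group names used in the report
#' @return A list of class \code{GroupComparison}: group sizes, medians, U,
#'   two-sided p, and \code{significant} (p < alpha).
#' @examples
#' gA <- data.frame(volume_id = "a", length_um = c(10, 12, 14),
#'                  avg_cross_section_um2 = 1)
#' gB <- data.frame(volume_id = "b", length_um = c(30, 35, 40),
#'                  avg_cross_section_um2 = 1)
#' compareGroups(gA, gB, "length_um")
#' @export
compareGroups <- function(groupA, groupB, feature = "length_um",
                          unit = c("segment", "volume_mean"), alpha = 0.05,
                          labels = c("A", "B")) {
  unit <- match.arg(unit)
  for (g in list(groupA, groupB))
    if (!all(c("volume_id", feature) %in% names(g)))
      stop("feature tables need columns volume_id and ", feature,
           call. = FALSE)
  pick <- function(g) {
    if (unit == "segment") return(g[[feature]])
    means <- tapply(g[[feature]], g$volume_id, mean)
    if (length(means) < 2L)
      stop("volume_mean unit needs at least 2 volumes per group",
           call. = FALSE)
    as.numeric(means)
  }
  va <- pick(groupA); vb <- pick(groupB)
  ut <- mannWhitneyU(va, vb)
  structure(list(
    feature = feature, unit = unit, alpha = alpha,
    labels = labels,
    n = c(length(va), length(vb)),
    median = c(median(va), median(vb)),
    u_statistic = ut@uStatistic,
    p_two_sided = ut@pTwoSided,
    method = ut@method,
    significant = ut@pTwoSided < alpha), class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s (%s unit)\n", x$feature, x$unit))
  cat(sprintf("  %s: n = %d, median = %.3g\n", x$labels[1], x$n[1],
              x$median[1]))
  cat(sprintf("  %s: n = %d, median = %.3g\n", x$labels[2], x$n[2],
              x$median[2]))
  cat(sprintf("  U = %g, two-sided p = %.4g (%s)%s\n", x$u_statistic,
              x$p_two_sided, x$method,
              if (x$significant) sprintf(" *significant at alpha = %g*",
                                         x$alpha) else ""))
  invisible(x)
}

#' Serialize a comparison report
#'
#' Writes a [compareGroups()] report as both CSV (one row) and JSON.
#'
#' @param comparison a \code{GroupComparison} (or list of them)
#' @param path output path without extension; \code{.csv} and \code{.json}
#'   are appended
#' @return The two paths, invisibly.
#' @export
writeComparison <- function(comparison, path) {
  if (inherits(comparison, "GroupComparison")) comparison <- list(comparison)
  rows <- do.call(rbind, lapply(comparison, function(x)
    data.frame(feature = x$feature, unit = x$unit,
               group_a = x$labels[1], group_b = x$labels[2],
               n_a = x$n[1], n_b = x$n[2],
               median_a = x$median[1], median_b = x$median[2],
               u_statistic = x$u_statistic, p_two_sided = x$p_two_sided,
               method = x$method, alpha = x$alpha,
               significant = x$significant)))
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  write.csv(rows, csv, row.names = FALSE)
  jsonlite::write_json(lapply(comparison, unclass), js, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(csv, js))
}
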