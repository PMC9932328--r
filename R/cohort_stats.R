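#' Median and interquartile range of a continuous variable
#'
#' Continuous endpoints are summarized as median and interquartile range
#' (Q1, Q3 via linear-interpolation quantiles); binary variables as
#' absolute and relative frequencies.
#'
#' @param values numeric vector; `NA`s are dropped with their count noted.
#' @return one-row tibble: `n`, `median`, `q1`, `q3`, `n_missing`.
#' @examples
#' qct_summary(c(1, 2, 3, 4, 5))
#' @export
qct_summary <- function(values) {
  n_miss <- sum(is.na(values))
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
                 n_missing = n_miss)
}

#' @rdname qct_summary
#' @param flags logical (or 0/1) vector.
#' @return for `summarize_binary`, a one-row tibble: `n`, `count`, `pct`.
#' @export
summarize_binary <- function(flags) {
  n_miss <- sum(is.na(flags))
  flags <- as.logical(flags[!is.na(flags)])
  if (length(flags) == 0L) stop("empty input", call. = FALSE)
  tibble::tibble(n = length(flags), count = sum(flags),
                 pct = 100 * mean(flags), n_missing = n_miss)
}

#' Friedman test across repeated visits
#'
#' Rank-based Friedman chi-square over a complete-block design (subjects x
#' timepoints) with average ranks for ties; subjects with a missing visit
#' are dropped and counted. For small designs (at most `exact_max`
#' enumerable within-subject orderings, default 10^5) the P-value comes
#' from the exact permutation distribution of the statistic; larger designs
#' use the chi-square reference distribution.
#'
#' @param blocks numeric matrix, rows = subjects, columns = timepoints.
#' @param exact_max largest number of within-block orderings, `(k!)^n`,
#'   still enumerated exactly.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `method`,
#'   `n_subjects_used`, `n_subjects_dropped`.
#' @export
friedman_qct <- function(blocks, exact_max = 1e5) {
  blocks <- as.matrix(blocks)
  if (ncol(blocks) < 2L) stop("need at least 2 timepoints", call. = FALSE)
  complete <- stats::complete.cases(blocks)
  dropped <- sum(!complete)
  blocks <- blocks[complete, , drop = FALSE]
  if (nrow(blocks) < 3L) stop("fewer than 3 complete subjects", call. = FALSE)
  n <- nrow(blocks); k <- ncol(blocks)
  if (all(apply(blocks, 1, function(r) length(unique(r)) == 1L))) {
    # identical columns within every block: statistic 0 by definition, but
    # friedman.test would divide by a zero tie correction
    return(tibble::tibble(statistic = 0, df = k - 1L, p_value = 1,
                          method = "degenerate", n_subjects_used = n,
                          n_subjects_dropped = dropped))
  }
  ft <- stats::friedman.test(blocks)
  stat <- unname(ft$statistic)
  n_arrangements <- factorial(k)^n
  if (n_arrangements <= exact_max) {
    p <- friedman_exact_p(blocks, stat)
    method <- "exact permutation"
  } else {
    p <- ft$p.value
    method <- "chi-square"
  }
  tibble::tibble(
    statistic = stat, df = unname(ft$parameter), p_value = p,
    method = method, n_subjects_used = n, n_subjects_dropped = dropped
  )
}

# exact permutation distribution of the Friedman statistic: each subject's
# rank vector is permuted independently; the per-subject distributions of
# column-rank contributions are convolved instead of enumerating (k!)^n
# arrangements directly, which is exact and far cheaper
friedman_exact_p <- function(blocks, stat) {
  k <- ncol(blocks)
  perms <- all_permutations(k)
  # per subject: all k! permuted rank vectors (ties keep average ranks)
  per_subject <- lapply(seq_len(nrow(blocks)), function(i) {
    r <- rank(blocks[i, ])
    t(apply(perms, 1, function(p) r[p]))
  })
  # distribution over column-rank-sum vectors, built by convolution
  dist <- list(`v` = matrix(0, 1, k), p = 1)
  colnames(dist$v) <- NULL
  for (rs in per_subject) {
    nv <- nrow(dist$v) * nrow(rs)
    v <- dist$v[rep(seq_len(nrow(dist$v)), each = nrow(rs)), , drop = FALSE] +
      rs[rep(seq_len(nrow(rs)), times = nrow(dist$v)), , drop = FALSE]
    p <- dist$p[rep(seq_along(dist$p), each = nrow(rs))] / nrow(rs)
    key <- apply(v, 1, paste, collapse = ",")
    agg <- rowsum(p, key)
    uv <- do.call(rbind, lapply(strsplit(rownames(agg), ","), as.numeric))
    dist <- list(v = uv, p = as.numeric(agg))
  }
  # statistic for each rank-sum vector, with the tie correction of the data
  n <- nrow(blocks)
  ties <- sum(apply(blocks, 1, function(row) {
    tl <- table(row); sum(tl^3 - tl)
  }))
  den <- n * k * (k + 1) - ties / (k - 1)
  stats_all <- 12 * rowSums((dist$v - n * (k + 1) / 2)^2) / den
  sum(dist$p[stats_all >= stat - 1e-10])
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind(rep(pos, nrow(sub)), sub + (sub >= pos))
  }))
}

#' McNemar test for paired binary variables
#'
#' Continuity-corrected McNemar chi-square on the 2x2 table of paired
#' binary outcomes.
#'
#' @param before,after logical (or 0/1) vectors of equal length.
#' @return one-row tibble: `statistic`, `p_value`, `n_discordant`.
#' @export
mcnemar_qct <- function(before, after) {
  before <- as.logical(before); after <- as.logical(after)
  ok <- !is.na(before) & !is.na(after)
  before <- before[ok]; after <- after[ok]
  if (length(before) == 0L) stop("no complete pairs", call. = FALSE)
  tab <- table(factor(before, c(FALSE, TRUE)), factor(after, c(FALSE, TRUE)))
  b <- tab[1, 2]; c2 <- tab[2, 1]
  if (b + c2 == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1, n_discordant = 0L))
  }
  # Edwards continuity correction, (|b - c| - 1)^2 / (b + c), against the
  # chi-square(1) reference
  stat <- (abs(b - c2) - 1)^2 / (b + c2)
  tibble::tibble(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 n_discordant = as.integer(b + c2))
}

#' Wilcoxon-Mann-Whitney test between two groups
#'
#' Exact enumeration when both groups have at most `exact_max` observations
#' and no ties; otherwise the tie-corrected normal approximation.
#'
#' @param group_a,group_b numeric vectors.
#' @param exact_max exact-enumeration size limit per group (default 8).
#' @return one-row tibble: `statistic` (Mann-Whitney U of group_a),
#'   `p_value`, `method`.
#' @export
wmw_test <- function(group_a, group_b, exact_max = 8L) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 1L || length(group_b) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- length(group_a) <= exact_max && length(group_b) <= exact_max &&
    !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact)
  )
  tibble::tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    method = if (exact) "exact" else "normal approximation, tie-corrected"
  )
}

#' Verbal strength rating of a Pearson correlation
#'
#' Bands: |r| < 0.2 very weak, 0.2-0.4 weak, 0.4-0.6 moderate, 0.6-0.8
#' strong, >= 0.8 very strong.
#'
#' @param r correlation coefficient(s).
#' @return character vector of ratings.
#' @export
rate_correlation <- function(r) {
  cut(abs(r), breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
      labels = c("very weak", "weak", "moderate", "strong", "very strong"),
      right = FALSE) |> as.character()
}

#' Pairwise Pearson correlation map with Benjamini-Hochberg adjustment
#'
#' Pearson correlations over all complete pairs for every unordered variable
#' pair, pooled across whatever rows the table contains (typically all
#' time points and lung lobes), with Fisher-z 95% confidence intervals,
#' Benjamini-Hochberg adjusted P-values over all off-diagonal cells, and
#' verbal strength ratings.
#'
#' @param data a data frame.
#' @param variables character vector of numeric column names (default: all
#'   numeric columns).
#' @return tibble, one row per unordered pair: `var1`, `var2`, `n`, `r`,
#'   `ci_lo`, `ci_hi`, `p_value`, `p_adj`, `rating`. Zero-variance cells
#'   carry `NA` estimates and a `degenerate` flag.
#' @export
correlation_map <- function(data, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
    variables <- variables[!startsWith(variables, ".")]
  }
  miss <- setdiff(variables, names(data))
  if (length(miss)) stop("variables not in data: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  pairs <- utils::combn(variables, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stop("fewer than 3 complete pairs for ",
                             pr[1], " ~ ", pr[2], call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(var1 = pr[1], var2 = pr[2], n = length(x),
                            r = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                            p_value = NA_real_, degenerate = TRUE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
    tibble::tibble(var1 = pr[1], var2 = pr[2], n = length(x),
                   r = unname(ct$estimate), ci_lo = ci[1], ci_hi = ci[2],
                   p_value = ct$p.value, degenerate = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$rating <- ifelse(is.na(out$r), NA_character_, rate_correlation(out$r))
  out
}
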