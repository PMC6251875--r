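# Correlation of experimental activities with docking-score / binding-energy
# tables: Pearson R2 with two-sided p-values, scans over score columns and
# conditions, and leave-one-point outlier sensitivity.

#' Two-sided p-value from a printed (R2, n) pair
#'
#' The p-value convention used throughout: a two-sided t-test on the Pearson
#' correlation, `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom (equivalent to the overall F-test of the simple regression). This
#' lets printed (R2, n) pairs be checked without the underlying data.
#'
#' @param r2 squared Pearson correlation, in `[0, 1)`.
#' @param n number of paired observations (>= 3).
#' @return two-sided p-value.
#' @examples
#' p_from_r2(0.10, 11)  # ~0.34
#' @export
p_from_r2 <- function(r2, n) {
  stopifnot(all(r2 >= 0 & r2 < 1), all(n >= 3))
  t <- sqrt(r2) * sqrt((n - 2) / (1 - r2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Pearson correlation with significance and per-point sensitivity
#'
#' Pearson r, R2 = r^2, the two-sided t-test p-value, the slope sign, and for
#' each point the change in R2 when that point is left out.
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite.
#' @return a one-row tibble (class `correlation_result`): `r`, `r_squared`,
#'   `p_value`, `n`, `slope_sign`; attribute `loo` is the per-point tibble
#'   (`point`, `r_squared_without`, `delta_r_squared`).
#' @export
corr_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  loo <- tibble::tibble(
    point = seq_len(n),
    r_squared_without = vapply(seq_len(n), function(i) {
      stats::cor(x[-i], y[-i])^2
    }, numeric(1))
  )
  loo$delta_r_squared <- r^2 - loo$r_squared_without
  out <- tibble::tibble(
    r = r,
    r_squared = r^2,
    p_value = ct$p.value,
    n = n,
    slope_sign = sign(r)
  )
  attr(out, "loo") <- loo
  class(out) <- c("correlation_result", class(out))
  out
}

#' Correlate a response against every score column of a table
#'
#' One [corr_with_p()] per score column (e.g. docking score and the binding
#' energies at each protein flexibility radius), joined to the response by
#' substrate id; rows present in only one table are dropped pairwise with a
#' message. The best cell (largest R2) is flagged.
#'
#' @param scores data frame: one id column plus numeric score columns;
#'   non-numeric columns other than `id_col` (e.g. pH, protein state labels)
#'   are treated as grouping conditions and carried through.
#' @param activity data frame with the id column and the response column.
#' @param response response column name in `activity`.
#' @param id_col shared id column name (default `"id"`).
#' @return tibble with one row per (condition, score column): `score`,
#'   condition columns, `r`, `r_squared`, `p_value`, `n`, `slope_sign`,
#'   `best` (logical).
#' @export
correlation_scan <- function(scores, activity, response, id_col = "id") {
  scores <- tibble::as_tibble(scores)
  activity <- tibble::as_tibble(activity)
  stopifnot(id_col %in% names(scores), id_col %in% names(activity),
            response %in% names(activity))
  joined <- dplyr::inner_join(scores, activity[c(id_col, response)],
                              by = id_col)
  if (nrow(joined) == 0) stop("no shared substrate ids", call. = FALSE)
  dropped <- nrow(scores) - nrow(joined)
  if (dropped > 0) {
    message(dropped, " score row(s) without matching activity dropped")
  }
  cond_cols <- setdiff(names(scores)[!vapply(scores, is.numeric, logical(1))],
                       id_col)
  score_cols <- setdiff(names(scores)[vapply(scores, is.numeric, logical(1))],
                        id_col)
  groups <- if (length(cond_cols)) {
    dplyr::group_split(dplyr::group_by(joined,
                                       dplyr::across(dplyr::all_of(cond_cols))))
  } else list(joined)
  res <- purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(score_cols, function(sc) {
      cc <- corr_with_p(g[[sc]], g[[response]])
      dplyr::bind_cols(
        tibble::tibble(score = sc),
        if (length(cond_cols)) g[1, cond_cols] else NULL,
        cc
      )
    })
  })
  res$best <- seq_len(nrow(res)) == which.max(res$r_squared)
  res
}

#' Leave-one-point outlier sensitivity of a correlation
#'
#' Recomputes R2 without each point; points whose removal changes R2 by more
#' than `flag_threshold` in absolute value are flagged as leverage points.
#'
#' @param x,y numeric vectors (n >= 4).
#' @param flag_threshold |delta R2| above which a point is flagged
#'   (default 0.15).
#' @return tibble of length n: `point`, `x`, `y`, `r_squared_without`,
#'   `delta_r_squared`, `leverage_flag`; attribute `r_squared_full`.
#' @export
outlier_sensitivity <- function(x, y, flag_threshold = 0.15) {
  if (length(x) < 4) stop("need at least 4 points", call. = FALSE)
  full <- corr_with_p(x, y)
  loo <- attr(full, "loo")
  out <- tibble::tibble(
    point = loo$point, x = x, y = y,
    r_squared_without = loo$r_squared_without,
    delta_r_squared = loo$delta_r_squared,
    leverage_flag = abs(loo$delta_r_squared) > flag_threshold
  )
  attr(out, "r_squared_full") <- full$r_squared
  out
}
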