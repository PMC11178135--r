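power_sse <- function(par, x, y) sum((y - par[1] * x^par[2])^2)

#' Fit a power function to a block trajectory
#'
#' Least-squares fit of y = a * x^b to per-block preferences over block
#' indices x = 1..n. The exponent b is the rate of change of preference:
#' values far from 0 indicate learning about the alternatives. Zeros in `y`
#' are clamped to 1e-6 so the fit stays defined for all-disadvantageous
#' trajectories. The fit is initialized from the exact log-log regression
#' (log y = log a + b log x) and refined by direct minimization of the
#' untransformed sum of squares.
#'
#' @param block_prefs numeric vector of non-negative preferences (at least
#'   3 of them).
#' @param x block indices (default `seq_along(block_prefs)`).
#' @return an `igt_power_fit`: list with `a`, `b`, `rmse`, `converged`.
#'   On optimizer failure `b` is `NaN` and `converged` is `FALSE`.
#' @export
#' @examples
#' fit_power(0.3 * (1:5)^0.5)  # recovers a = 0.3, b = 0.5
fit_power <- function(block_prefs, x = seq_along(block_prefs)) {
  if (length(block_prefs) < 3)
    stop("need at least 3 blocks to fit a power function", call. = FALSE)
  if (any(block_prefs < 0))
    stop("`block_prefs` must be non-negative", call. = FALSE)
  stopifnot(length(x) == length(block_prefs), all(x > 0))
  y <- pmax(block_prefs, 1e-6)
  res <- tryCatch({
    co <- coef(lm(log(y) ~ log(x)))
    start <- c(a = exp(co[[1]]), b = co[[2]])
    o1 <- optim(start, power_sse, x = x, y = y, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 2000))
    o2 <- optim(o1$par, power_sse, x = x, y = y, method = "BFGS",
                control = list(reltol = 1e-14, maxit = 500))
    best <- if (o2$value <= o1$value) o2 else o1
    list(a = unname(best$par[1]), b = unname(best$par[2]),
         rmse = sqrt(best$value / length(y)), converged = TRUE)
  }, error = function(e) list(a = NA_real_, b = NaN, rmse = NA_real_,
                              converged = FALSE))
  structure(res, class = "igt_power_fit")
}

#' @export
print.igt_power_fit <- function(x, ...) {
  cat(sprintf("power fit y = a x^b: a = %.4g, b = %.4g (rmse %.4g)%s\n",
              x$a, x$b, x$rmse,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Partition a cohort into preference quartile subgroups
#'
#' Q1: overall preference strictly below the first quartile; Q3: at or
#' above the third quartile; Q2: in between. Quartiles are computed with
#' linear interpolation (`quantile()` type 7) within the cohort being
#' partitioned, so a degenerate cohort with all preferences equal lands
#' entirely in Q3 (the at-or-above rule holds with equality).
#'
#' @param overall_prefs per-subject overall preference proportions
#'   (>= 4 subjects).
#' @param subject_ids optional identifiers (default `s1`, `s2`, ...).
#' @return a data frame with columns `subject_id`, `overall_preference`,
#'   `subgroup` (one of `"Q1"`, `"Q2"`, `"Q3"`).
#' @export
#' @examples
#' quartile_subgroups(c(0.1, 0.2, 0.8, 0.9))
quartile_subgroups <- function(overall_prefs,
                               subject_ids = paste0("s", seq_along(overall_prefs))) {
  if (length(overall_prefs) < 4)
    stop("need at least 4 subjects to form quartile subgroups",
         call. = FALSE)
  stopifnot(length(subject_ids) == length(overall_prefs))
  q <- quantile(overall_prefs, c(0.25, 0.75), type = 7, names = FALSE)
  sub <- ifelse(overall_prefs < q[1], "Q1",
                ifelse(overall_prefs >= q[2], "Q3", "Q2"))
  data.frame(subject_id = subject_ids,
             overall_preference = overall_prefs,
             subgroup = sub, stringsAsFactors = FALSE)
}

#' Correlation and RMSE between two block-mean trajectories
#'
#' Pearson correlation (two-sided test) plus root-mean-square error between
#' paired block means, e.g. a participant group's block means against its
#' fitted agents' block means with the final block excluded (that block
#' having served as the fitting objective). Matrix inputs — subgroup-by-
#' block mean tables — are flattened before pairing.
#'
#' @param human_block_means numeric vector or matrix.
#' @param agent_block_means numeric vector or matrix, same length.
#' @return a list with `r`, `p`, `rmse`, `n`, and `defined` (`FALSE` when
#'   either input has zero variance, in which case `r` and `p` are `NA`).
#' @export
#' @examples
#' correlate_blocks(c(0.2, 0.4, 0.6, 0.8), c(0.25, 0.35, 0.65, 0.75))
correlate_blocks <- function(human_block_means, agent_block_means) {
  x <- as.vector(human_block_means)
  y <- as.vector(agent_block_means)
  if (length(x) != length(y))
    stop("block-mean vectors must have equal length", call. = FALSE)
  rmse <- sqrt(mean((x - y)^2))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, rmse = rmse, n = length(x),
                defined = FALSE))
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, rmse = rmse, n = length(x),
       defined = TRUE)
}

#' Per-subject summary of a targets table
#'
#' For each subject: block preferences, overall preference (mean of
#' blocks), quartile subgroup within the cohort, and the power-function
#' rate-of-change fit.
#'
#' @param targets a targets data frame (`subject_id`, `group`, `b1`..`bK`).
#' @return a data frame with columns `subject_id`, `group`, `b1`..`bK`,
#'   `overall_pref`, `subgroup`, `power_a`, `power_b`, `power_rmse`.
#' @export
summarize_cohort <- function(targets) {
  bcols <- grep("^b[0-9]+$", names(targets), value = TRUE)
  if (length(bcols) < 3)
    stop("`targets` must have at least 3 block columns b1..bK",
         call. = FALSE)
  bp <- as.matrix(targets[, bcols])
  overall <- rowMeans(bp)
  sub <- quartile_subgroups(overall, targets$subject_id)
  pw <- t(vapply(seq_len(nrow(bp)), function(i) {
    f <- fit_power(bp[i, ])
    c(f$a, f$b, f$rmse)
  }, numeric(3)))
  out <- targets[, c("subject_id",
                     intersect("group", names(targets)), bcols)]
  out$overall_pref <- overall
  out$subgroup <- sub$subgroup
  out$power_a <- pw[, 1]
  out$power_b <- pw[, 2]
  out$power_rmse <- pw[, 3]
  out
}

#' Subgroup-by-block mean preference matrix
#'
#' Mean block preference per quartile subgroup, the matrix shape the
#' participant-versus-agent correlation operates on (optionally with the
#' final block dropped).
#'
#' @param targets a targets data frame.
#' @param drop_last drop the final block (default `TRUE`, matching its use
#'   as the fitting objective).
#' @return a numeric matrix, rows `Q1`/`Q2`/`Q3` (those present), columns
#'   blocks.
#' @export
subgroup_block_means <- function(targets, drop_last = TRUE) {
  bcols <- grep("^b[0-9]+$", names(targets), value = TRUE)
  bp <- as.matrix(targets[, bcols])
  sub <- quartile_subgroups(rowMeans(bp), targets$subject_id)$subgroup
  if (drop_last) bp <- bp[, -ncol(bp), drop = FALSE]
  groups <- sort(unique(sub))
  m <- t(vapply(groups, function(g) colMeans(bp[sub == g, , drop = FALSE]),
                numeric(ncol(bp))))
  rownames(m) <- groups
  colnames(m) <- head(bcols, ncol(bp))
  m
}
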