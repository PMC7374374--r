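#' Dice overlap coefficient
#'
#' `D = 2 |A intersect B| / (|A| + |B|)` between two binary masks of equal
#' size. Two empty masks are defined to agree perfectly (`D = 1`), with a
#' warning.
#'
#' @param a,b binary mask matrices of identical dimensions.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot_same_dim(a, b, "masks")
  assert_binary_mask(a, "a"); assert_binary_mask(b, "b")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    warning("both masks are empty; Dice defined as 1 by convention")
    return(1)
  }
  2 * sum(a * b) / (sa + sb)
}

#' Per-group area statistics
#'
#' Pixel-count areas of a set of masks, summarized per group tag (mean,
#' median, quartiles). 2D "volumes" are pixel areas throughout.
#'
#' @param masks list of binary mask matrices.
#' @param labels group tag per mask (character or factor, recycled checks
#'   apply: must match `length(masks)`).
#' @return data.frame with one row per group: `group`, `n`, `mean`,
#'   `median`, `q1`, `q3`.
#' @export
group_area_stats <- function(masks, labels) {
  if (length(masks) != length(labels))
    stop("one group label per mask is required")
  if (length(masks) == 0) stop("empty mask list")
  areas <- vapply(masks, sum, numeric(1))
  labels <- as.character(labels)
  groups <- unique(labels)
  out <- do.call(rbind, lapply(groups, function(gp) {
    a <- areas[labels == gp]
    data.frame(group = gp, n = length(a), mean = mean(a),
               median = median(a),
               q1 = unname(quantile(a, 0.25)),
               q3 = unname(quantile(a, 0.75)))
  }))
  rownames(out) <- NULL
  out
}

#' Intraclass correlation coefficient
#'
#' Single-measure two-way ICC between paired measurements, computed from
#' the two-way ANOVA mean squares. The default `"agreement"` flavor is
#' ICC(2,1) (two-way random effects, absolute agreement), the usual choice
#' for method-versus-manual volume comparisons; `"consistency"` gives
#' ICC(3,1), which ignores a fixed additive bias.
#'
#' @param x,y numeric vectors of equal length (>= 3): the paired
#'   measurements (e.g. estimated and manual areas).
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return scalar ICC in `[-1, 1]`.
#' @export
icc <- function(x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) stop("at least 3 pairs are required")
  if (var(x) == 0 && var(y) == 0)
    stop("both measurement lists have zero variance; ICC undefined")
  X <- cbind(x, y)
  k <- 2
  grand <- mean(X)
  row_m <- rowMeans(X); col_m <- colMeans(X)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SSE <- sum((X - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (type == "agreement")
    (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  else
    (MSR - MSE) / (MSR + (k - 1) * MSE)
}

#' Bland-Altman agreement analysis
#'
#' Bias and 95% limits of agreement of `y - x`: `bias = mean(y - x)`,
#' limits `bias +/- 1.96 * sd(y - x)`, plus the per-pair scatter
#' coordinates (mean, difference).
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return list with `bias`, `lower`, `upper`, `sd_diff`, and a data.frame
#'   `points` with columns `mean` and `diff`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2) stop("at least 2 pairs are required")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       sd_diff = s,
       points = data.frame(mean = (x + y) / 2, diff = d))
}

#' Agreement report between estimated and truth masks
#'
#' Per-item Dice and areas plus summary agreement statistics (area ICC and
#' Bland-Altman bias/limits of the estimated vs truth areas).
#'
#' @param est,truth lists of binary mask matrices, paired.
#' @param groups optional group tag per item.
#' @param ids optional item identifiers.
#' @return list of class `lbseg_eval_report`: `items` (data.frame with
#'   `id`, `group`, `area_est`, `area_truth`, `dice`), `icc`,
#'   `bland_altman`, `group_stats` (or `NULL` when no groups given).
#' @export
eval_report <- function(est, truth, groups = NULL, ids = NULL) {
  if (length(est) != length(truth)) stop("`est` and `truth` must pair up")
  n <- length(est)
  if (is.null(ids)) ids <- seq_len(n)
  if (is.null(groups)) grp <- rep("all", n) else grp <- as.character(groups)
  items <- data.frame(
    id = ids, group = grp,
    area_est = vapply(est, sum, numeric(1)),
    area_truth = vapply(truth, sum, numeric(1)),
    dice = vapply(seq_len(n), function(i) dice(est[[i]], truth[[i]]),
                  numeric(1)))
  structure(list(
    items = items,
    icc = if (n >= 3) icc(items$area_truth, items$area_est) else NA_real_,
    bland_altman = if (n >= 2) bland_altman(items$area_truth,
                                            items$area_est) else NULL,
    group_stats = if (!is.null(groups))
      group_area_stats(est, groups) else NULL),
    class = "lbseg_eval_report")
}

#' @export
print.lbseg_eval_report <- function(x, ...) {
  cat(sprintf("<lbseg_eval_report> %d items, mean Dice %.3f",
              nrow(x$items), mean(x$items$dice)))
  if (!is.na(x$icc)) cat(sprintf(", area ICC %.3f", x$icc))
  if (!is.null(x$bland_altman))
    cat(sprintf(", BA bias %.1f px [%.1f, %.1f]", x$bland_altman$bias,
                x$bland_altman$lower, x$bland_altman$upper))
  cat("\n")
  invisible(x)
}

#' Write an agreement report to CSV + JSON
#'
#' The per-item table goes to `<stem>.csv`, the summary (ICC, Bland-Altman
#' bias/limits, per-group stats) to `<stem>.json`.
#'
#' @param report an [eval_report()].
#' @param stem output path without extension.
#' @return invisibly, the two file paths.
#' @export
write_eval_report <- function(report, stem) {
  stopifnot(inherits(report, "lbseg_eval_report"))
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  write.csv(report$items, csv, row.names = FALSE)
  summ <- list(
    n = nrow(report$items),
    mean_dice = mean(report$items$dice),
    icc = report$icc,
    ba_bias = if (is.null(report$bland_altman)) NULL
              else report$bland_altman$bias,
    ba_limits = if (is.null(report$bland_altman)) NULL
                else c(report$bland_altman$lower, report$bland_altman$upper),
    group_stats = report$group_stats)
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv = csv, json = js))
}
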