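#' Construct a meta-analysis dataset
#'
#' A `meta_dataset` is a data frame of effect-size observations grouped by
#' independent study or data sample.  Each row carries a point estimate `y`,
#' its sampling standard error `se` (taken as known), and a `group_id`
#' identifying the independent group it came from.  Optional moderator
#' columns (`method`, `statistic`, `data_year`, `income`, plus any extra
#' numeric columns) are carried through for use in meta-regression.
#'
#' @param data A data frame with at least columns `group_id`, `y`, `se`.
#'   `method`, if present, must be `"RP"` or `"SP"` (revealed vs stated
#'   preference); `statistic`, if present, must be `"mean"` or `"median"`.
#' @param units Character scalar describing the units of `y` and `se`,
#'   carried as metadata only.  Default `"million 2020 USD"`.
#' @return An object of class `meta_dataset` (a validated data frame).
#' @examples
#' d <- meta_dataset(data.frame(
#'   group_id = c("A", "A", "B"), y = c(9, 11, 10), se = c(1, 1, 2)))
#' n_groups(d)
#' group_sizes(d)
#' @export
meta_dataset <- function(data, units = "million 2020 USD") {
  if (!is.data.frame(data)) stop("`data` must be a data frame")
  req <- c("group_id", "y", "se")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0) stop("dataset is empty: no estimable data")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$group_id <- as.character(data$group_id)
  data$y <- as.numeric(data$y)
  data$se <- as.numeric(data$se)
  bad_y <- which(!is.finite(data$y))
  if (length(bad_y) > 0)
    stop("non-finite or non-numeric `y` in row(s): ",
         paste(bad_y, collapse = ", "))
  bad_se <- which(!is.finite(data$se) | data$se <= 0)
  if (length(bad_se) > 0)
    stop("`se` must be strictly positive and finite; offending row(s): ",
         paste(bad_se, collapse = ", "))
  if ("method" %in% names(data)) {
    ok <- is.na(data$method) | data$method %in% c("RP", "SP")
    if (!all(ok))
      stop("`method` must be 'RP' or 'SP'; offending row(s): ",
           paste(which(!ok), collapse = ", "))
  }
  if ("statistic" %in% names(data)) {
    ok <- is.na(data$statistic) | data$statistic %in% c("mean", "median")
    if (!all(ok))
      stop("`statistic` must be 'mean' or 'median'; offending row(s): ",
           paste(which(!ok), collapse = ", "))
  }
  attr(data, "units") <- units
  class(data) <- c("meta_dataset", "data.frame")
  data
}

#' @rdname meta_dataset
#' @param x A `meta_dataset`.
#' @export
n_groups <- function(x) length(unique(x$group_id))

#' @rdname meta_dataset
#' @export
group_sizes <- function(x) {
  tab <- table(x$group_id)
  # preserve first-appearance order of groups
  ord <- unique(x$group_id)
  stats::setNames(as.integer(tab[ord]), ord)
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf("meta_dataset: %d observations in %d groups [%s]\n",
              nrow(x), n_groups(x), attr(x, "units")))
  NextMethod()
}

# canonical column order for serialization
.meta_canonical <- c("group_id", "y", "se", "method", "statistic",
                     "data_year", "income")

#' Read a meta-analysis dataset from CSV
#'
#' Reads an RFC-4180 CSV (UTF-8, header required) into a [meta_dataset].
#' Canonical columns are `group_id, y, se, method, statistic, data_year,
#' income`; any extra columns are ingested as named moderators.  A `schema`
#' mapping allows files with different column names.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(group_id = "study", y = "vsl")`.
#' @param units Units label stored on the result.
#' @return A [meta_dataset].
#' @export
read_meta_csv <- function(path, schema = NULL, units = "million 2020 USD") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop("schema column not found in file: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  miss <- setdiff(c("group_id", "y", "se"), names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  meta_dataset(df, units = units)
}

#' Write a meta-analysis dataset to CSV
#'
#' Lossless inverse of [read_meta_csv()]: canonical columns first, extra
#' moderators after, UTF-8 with header.
#'
#' @param dataset A [meta_dataset].
#' @param path Output file path.
#' @export
write_meta_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "meta_dataset"))
  present <- intersect(.meta_canonical, names(dataset))
  extra <- setdiff(names(dataset), .meta_canonical)
  out <- as.data.frame(dataset)[, c(present, extra), drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Subset a meta-analysis dataset by study type and statistic
#'
#' Filters by primary estimation method (revealed preference `"RP"`, stated
#' preference `"SP"`, or `"pooled"` for both) and by statistic pooling:
#' `"mm"` keeps both mean and median observations, `"m"` keeps means only.
#' Groups emptied by the filter are dropped.
#'
#' @param dataset A [meta_dataset].
#' @param method One of `"pooled"`, `"RP"`, `"SP"`.
#' @param statistic One of `"mm"`, `"m"`.
#' @return A [meta_dataset]; error if the filter empties it.
#' @export
subset_meta <- function(dataset, method = c("pooled", "RP", "SP"),
                        statistic = c("mm", "m")) {
  stopifnot(inherits(dataset, "meta_dataset"))
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  keep <- rep(TRUE, nrow(dataset))
  if (method != "pooled") {
    if (!"method" %in% names(dataset))
      stop("dataset has no `method` column; cannot filter by study type")
    keep <- keep & !is.na(dataset$method) & dataset$method == method
  }
  if (statistic == "m" && "statistic" %in% names(dataset)) {
    # rows with no statistic label are treated as means
    keep <- keep & (is.na(dataset$statistic) | dataset$statistic == "mean")
  }
  out <- dataset[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("filter (method=", method, ", statistic=", statistic,
         ") leaves no estimable data")
  rownames(out) <- NULL
  attr(out, "units") <- attr(dataset, "units")
  class(out) <- c("meta_dataset", "data.frame")
  out
}

#' Balanced combination of independent syntheses
#'
#' The balanced estimate is the simple average of the revealed-preference
#' and stated-preference syntheses, placing equal weight on the two study
#' types regardless of how many observations each contributes.  Under
#' independence its standard error is half the root-sum-of-squares of the
#' two input standard errors.
#'
#' @param est_rp,est_sp [meta_estimate] objects, or numeric scalars (then
#'   `se` is unavailable).
#' @return A [meta_estimate] with `method_label = "balanced"`.
#' @export
balanced_combine <- function(est_rp, est_sp) {
  get_est <- function(e) if (inherits(e, "meta_estimate")) e$estimate else as.numeric(e)
  get_se <- function(e) if (inherits(e, "meta_estimate")) e$se else NA_real_
  y1 <- get_est(est_rp); y2 <- get_est(est_sp)
  s1 <- get_se(est_rp); s2 <- get_se(est_sp)
  est <- (y1 + y2) / 2
  se <- if (is.na(s1) || is.na(s2)) NA_real_ else 0.5 * sqrt(s1^2 + s2^2)
  new_meta_estimate(
    estimate = est, se = se,
    se_method = if (is.na(se)) "unavailable" else "independence",
    group_estimates = c(RP = y1, SP = y2),
    weights = data.frame(group_id = c("RP", "SP"), row = NA_integer_,
                         w = c(0.5, 0.5)),
    components = NULL, n_groups = 2L, n_obs = 2L,
    method_label = "balanced")
}

#' Root mean squared error against an unbiased benchmark
#'
#' Treats the means-only (`m`) estimate as unbiased and measures the focal
#' (`mm`, pooled mean-and-median) estimate's RMSE as
#' \eqn{\sqrt{se_{mm}^2 + (\hat Y_{mm} - \hat Y_m)^2}}.  When the two
#' estimates coincide this reduces to the focal standard error.
#'
#' @param estimate_mm,se_mm Focal estimate and its standard error.
#' @param estimate_m Benchmark estimate assumed unbiased.
#' @return The RMSE (same units as the estimates).
#' @export
rmse_vs_unbiased <- function(estimate_mm, se_mm, estimate_m) {
  stopifnot(se_mm >= 0)
  sqrt(se_mm^2 + (estimate_mm - estimate_m)^2)
}
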