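#' Summary time series of percent occluded area for one group
#'
#' One paste under one saliva condition: the observation days and the
#' per-day mean, standard deviation and group size of the percent
#' occluded tubule area. This is the summary form in which the brushing
#' experiment's results are published (specimen-level values are not),
#' and the unit on which fitting and group comparison operate.
#'
#' @param paste Paste label, e.g. `"EB@TiO2"`.
#' @param condition Saliva condition: `"with_saliva"` or
#'   `"without_saliva"`. The table shorthands `"S"` and `"WS"` are
#'   accepted as aliases.
#' @param days Strictly increasing numeric vector of day indices (>= 1).
#' @param means Per-day mean percent occluded area, each in `[0, 100]`.
#' @param sds Per-day standard deviations, each >= 0.
#' @param n Number of specimens in the group (a single integer >= 1).
#'
#' @return An object of class `"occlusion_series"`.
#' @export
occlusion_series <- function(paste, condition, days, means, sds, n) {
  condition <- normalize_condition(condition)
  days <- as.numeric(days); means <- as.numeric(means); sds <- as.numeric(sds)
  if (length(days) == 0L || length(days) != length(means) ||
      length(days) != length(sds))
    stop("'days', 'means' and 'sds' must be non-empty and of equal length",
         call. = FALSE)
  if (any(!is.finite(days)) || any(diff(days) <= 0))
    stop("'days' must be finite and strictly increasing", call. = FALSE)
  if (any(days < 1)) stop("'days' must be >= 1", call. = FALSE)
  if (any(!is.finite(means)) || any(means < 0) || any(means > 100))
    stop("'means' must lie in [0, 100]", call. = FALSE)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("'sds' must be non-negative", call. = FALSE)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a single integer >= 1", call. = FALSE)
  structure(list(paste = as.character(paste), condition = condition,
                 days = days, means = means, sds = sds, n = n),
            class = "occlusion_series")
}

normalize_condition <- function(x) {
  if (length(x) != 1L) stop("'condition' must be a single label", call. = FALSE)
  key <- tolower(as.character(x))
  map <- c(s = "with_saliva", with_saliva = "with_saliva",
           saliva = "with_saliva",
           ws = "without_saliva", without_saliva = "without_saliva")
  if (!key %in% names(map))
    stop("unknown condition '", x, "'; use 'with_saliva'/'S' or ",
         "'without_saliva'/'WS'", call. = FALSE)
  unname(map[key])
}

#' @export
print.occlusion_series <- function(x, ...) {
  cat(sprintf("Occlusion series: %s, %s (n = %d specimens)\n",
              x$paste, x$condition, x$n))
  df <- data.frame(day = x$days, mean = x$means, sd = x$sds)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.occlusion_series <- function(x, ...) {
  data.frame(paste = x$paste, condition = x$condition, day = x$days,
             mean = x$means, sd = x$sds, n = x$n,
             stringsAsFactors = FALSE)
}

series_key <- function(s) paste(s$paste, s$condition, sep = " / ")

#' Published seven-day occlusion summaries (bundled dataset)
#'
#' The mean and standard deviation of the percent occluded tubule area
#' for three desensitizing pastes (an eggshell-titanium dioxide
#' composite, a proargin paste and a NovaMin paste) brushed twice daily
#' for seven days, with and without artificial-saliva immersion between
#' brushings; seven specimens per group. These 42 summary cells are the
#' complete published data of the brushing experiment and the default
#' input to [fit_occlusion_table()] and [compare_conditions()].
#'
#' @return A list of six [occlusion_series()] objects (3 pastes x 2
#'   conditions), each with 7 days and n = 7.
#'
#' @examples
#' tab <- occlusion_table1()
#' names(tab)
#'
#' @export
occlusion_table1 <- function() {
  path <- system.file("extdata", "table1_summary.csv", package = "occlufit",
                      mustWork = TRUE)
  read_occlusion_csv(path, format = "summary")
}

#' Published logistic occlusion rates
#'
#' The occlusion rate estimates published alongside the bundled summary
#' data, one per paste x saliva condition. Useful as ground truth for
#' parameter-recovery simulations.
#'
#' @return A data frame with columns `paste`, `condition` and `r`
#'   (per day).
#' @export
published_rates <- function() {
  path <- system.file("extdata", "published_rates.csv", package = "occlufit",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$condition <- vapply(df$condition, normalize_condition, character(1))
  df
}

#' Read occlusion time series from CSV
#'
#' Two schemas are understood. The long format has one row per specimen
#' per day with columns `paste, condition, specimen, day, occluded_pct`;
#' it is aggregated to per-group summaries. The summary format has
#' columns `paste, condition, day, mean, sd, n`. With `format = "auto"`
#' the schema is detected from the header.
#'
#' @param path Path to a CSV file with a header row.
#' @param format `"auto"`, `"long"` or `"summary"`.
#'
#' @return A list of [occlusion_series()] objects, one per paste x
#'   condition, named `"<paste> / <condition>"`.
#'
#' @seealso [write_occlusion_csv()], [occlusion_table1()]
#' @export
read_occlusion_csv <- function(path, format = c("auto", "long", "summary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  long_cols <- c("paste", "condition", "specimen", "day", "occluded_pct")
  sum_cols <- c("paste", "condition", "day", "mean", "sd", "n")
  if (format == "auto") {
    format <- if (all(long_cols %in% names(df))) "long"
              else if (all(sum_cols %in% names(df))) "summary"
              else stop("cannot detect schema from header: ",
                        paste(names(df), collapse = ", "), call. = FALSE)
  }
  need <- if (format == "long") long_cols else sum_cols
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$day)) || any(df$day < 1))
    stop("'day' must be >= 1 (first offending row: ",
         which(!(is.finite(df$day) & df$day >= 1))[1], ")", call. = FALSE)
  if (format == "long") {
    bad <- which(!is.finite(df$occluded_pct) | df$occluded_pct < 0 |
                   df$occluded_pct > 100)
    if (length(bad) > 0L)
      stop("'occluded_pct' outside [0, 100] at data row ", bad[1],
           call. = FALSE)
    aggregate_long(df)
  } else {
    bad <- which(!is.finite(df$mean) | df$mean < 0 | df$mean > 100)
    if (length(bad) > 0L)
      stop("'mean' outside [0, 100] at data row ", bad[1], call. = FALSE)
    bad <- which(!is.finite(df$sd) | df$sd < 0)
    if (length(bad) > 0L)
      stop("'sd' negative or non-finite at data row ", bad[1], call. = FALSE)
    key <- paste(df$paste, df$condition, df$day)
    if (anyDuplicated(key))
      stop("duplicate (paste, condition, day) at data row ",
           which(duplicated(key))[1], call. = FALSE)
    summaries_to_series(df)
  }
}

aggregate_long <- function(df) {
  key <- paste(df$paste, df$condition, df$specimen, df$day)
  if (anyDuplicated(key))
    stop("duplicate (paste, condition, specimen, day) at data row ",
         which(duplicated(key))[1], call. = FALSE)
  agg <- stats::aggregate(occluded_pct ~ paste + condition + day, data = df,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(paste = agg$paste, condition = agg$condition,
                    day = agg$day,
                    mean = agg$occluded_pct[, "mean"],
                    sd = ifelse(is.na(agg$occluded_pct[, "sd"]), 0,
                                agg$occluded_pct[, "sd"]),
                    n = agg$occluded_pct[, "n"],
                    stringsAsFactors = FALSE)
  summaries_to_series(out)
}

summaries_to_series <- function(df) {
  groups <- unique(df[, c("paste", "condition")])
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    sel <- df$paste == groups$paste[i] & df$condition == groups$condition[i]
    sub <- df[sel, , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    if (length(unique(sub$n)) > 1L)
      stop("group ", groups$paste[i], "/", groups$condition[i],
           " has varying 'n' across days", call. = FALSE)
    out[[i]] <- occlusion_series(groups$paste[i], groups$condition[i],
                                 sub$day, sub$mean, sub$sd, sub$n[1])
  }
  names(out) <- vapply(out, series_key, character(1))
  out
}

#' Write occlusion series to a summary-format CSV
#'
#' @param series A list of [occlusion_series()] objects (or a single
#'   one).
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_occlusion_csv <- function(series, path) {
  if (inherits(series, "occlusion_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
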