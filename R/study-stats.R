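#' Summary statistics of a numeric sample
#'
#' Mean, sample SD (n - 1 denominator), median and quartiles by linear
#' interpolation between order statistics at rank 1 + p(n - 1) (R's default
#' quantile type 7), plus min and max. For a single value the SD is
#' reported as 0 with \code{sd_defined = FALSE}.
#'
#' @param values non-empty numeric vector.
#' @return one-row data.frame: n, mean, sd, median, q1, q3, min, max,
#'   sd_defined.
#' @examples
#' summaryStats(c(10746, 10750, 10749))  # mean 10748, sd 2 (rounded)
#' @export
summaryStats <- function(values) {
    if (!is.numeric(values) || length(values) == 0L)
        stop("values must be a non-empty numeric vector")
    if (any(!is.finite(values))) stop("values must be finite")
    n <- length(values)
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(
        n = n,
        mean = mean(values),
        sd = if (n > 1L) stats::sd(values) else 0,
        median = q[2], q1 = q[1], q3 = q[3],
        min = min(values), max = max(values),
        sd_defined = n > 1L)
}

#' Simple linear regression with R-squared
#'
#' Ordinary least squares of y on x via [stats::lm()]. For simple
#' regression the reported r_squared equals the squared Pearson
#' correlation.
#'
#' @param x,y numeric vectors of equal length (at least 3); x must not be
#'   constant.
#' @return list with slope, intercept, r_squared, n.
#' @examples
#' olsFit(1:10, 2 * (1:10) + 1)$r_squared  # 1
#' @export
olsFit <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need at least 3 observations")
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) stop("need at least 3 finite observation pairs")
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0) stop("x is constant: regression undefined")
    if (stats::sd(y) == 0) stop("y is constant: R-squared undefined")
    fit <- stats::lm(y ~ x)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         n = length(x))
}

# surrogate columns regressed on the open-fiber count, in reporting order
.surrogateColumns <- c(
    "dry_mass_g", "visual_dialyzer", "visual_chamber", "rinse_back_ml",
    "delta_arterial_mmhg", "delta_venous_mmhg", "delta_tmp_mmhg",
    "delta_bvm_pct", "delta_ocm_ml_min")

#' Surrogate-parameter regression panel
#'
#' One simple regression per surrogate parameter with the open-fiber count
#' (\code{n_open_ref70}) as the independent variable, reporting R-squared
#' per column. Ordinal visual scores are treated as numeric. A column that
#' cannot be regressed (e.g. constant) is flagged in \code{note} with NA
#' estimates; the other columns are unaffected.
#'
#' @param records data.frame with column n_open_ref70 plus the surrogate
#'   columns (see [loadTable2Fixture()] for the schema); at least 3 rows.
#' @return data.frame: parameter, slope, intercept, r_squared, n, note.
#' @examples
#' panel <- surrogatePanel(loadTable2Fixture())
#' panel[panel$parameter == "dry_mass_g", "r_squared"]  # ~0.62
#' @export
surrogatePanel <- function(records) {
    if (!"n_open_ref70" %in% names(records))
        stop("records needs an n_open_ref70 column")
    if (nrow(records) < 3L) stop("need at least 3 records")
    cols <- intersect(.surrogateColumns, names(records))
    if (length(cols) == 0L) stop("no surrogate columns found")
    rows <- lapply(cols, function(cn) {
        fit <- tryCatch(olsFit(records$n_open_ref70, records[[cn]]),
                        error = function(e) e)
        if (inherits(fit, "error"))
            data.frame(parameter = cn, slope = NA_real_,
                       intercept = NA_real_, r_squared = NA_real_,
                       n = NA_integer_, note = conditionMessage(fit),
                       stringsAsFactors = FALSE)
        else
            data.frame(parameter = cn, slope = fit$slope,
                       intercept = fit$intercept,
                       r_squared = fit$r_squared, n = fit$n, note = "",
                       stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

.fixturePath <- function(name) {
    p <- system.file("extdata", name, package = "dialyzerCT")
    if (p == "") stop("packaged fixture not found: ", name)
    p
}

#' Packaged fiber-count table (per dialyzer, slice and threshold)
#'
#' Counts of open fibers for 3 non-used (blanco) and 20 used dialyzers in
#' the reference slice at the 60/70/80% thresholds and in a slice 2.5 mm
#' proximal of it at 70%, with the published percent differences. Schema-
#' validated on load.
#'
#' @return data.frame with columns dialyzer_id, group, n_ref70, n_offset70,
#'   pct_offset70, n_ref60, pct_ref60, n_ref80, pct_ref80.
#' @examples
#' nrow(loadTable1Fixture())  # 23
#' @export
loadTable1Fixture <- function() {
    df <- utils::read.csv(.fixturePath("table1_fiber_counts.csv"),
                          comment.char = "#", stringsAsFactors = FALSE)
    need <- c("dialyzer_id", "group", "n_ref70", "n_offset70",
              "pct_offset70", "n_ref60", "pct_ref60", "n_ref80", "pct_ref80")
    if (!identical(names(df), need))
        stop("table1 fixture schema mismatch")
    if (nrow(df) != 23L || sum(df$group == "blanco") != 3L ||
        sum(df$group == "used") != 20L)
        stop("table1 fixture must hold 3 blanco + 20 used dialyzers")
    cnt <- c("n_ref70", "n_offset70", "n_ref60", "n_ref80")
    if (any(sapply(df[cnt], function(v) any(v < 0 | v != round(v)))))
        stop("table1 fixture counts must be non-negative integers")
    df
}

#' Packaged surrogate-parameter table (per dialysis session)
#'
#' Open-fiber count plus the surrogate parameters of each of the 20
#' sessions: dialyzer dry mass, visual scores, rinse-back volume and the
#' interdialytic machine-parameter changes. Schema-validated on load.
#'
#' @return data.frame with columns dialyzer_id, n_open_ref70 and the nine
#'   surrogate columns.
#' @examples
#' loadTable2Fixture()$n_open_ref70[8]  # 534
#' @export
loadTable2Fixture <- function() {
    df <- utils::read.csv(.fixturePath("table2_surrogates.csv"),
                          comment.char = "#", stringsAsFactors = FALSE)
    need <- c("dialyzer_id", "n_open_ref70", .surrogateColumns)
    if (!identical(names(df), need))
        stop("table2 fixture schema mismatch")
    if (nrow(df) != 20L)
        stop("table2 fixture must hold 20 sessions")
    if (!all(df$visual_dialyzer %in% 1:4) ||
        !all(df$visual_chamber %in% 1:4))
        stop("visual scores must be in 1..4")
    if (any(df$n_open_ref70 < 0)) stop("n_open_ref70 must be >= 0")
    df
}

#' Long-format counts from the packaged fiber-count table
#'
#' Reshapes the wide per-dialyzer table into one row per (dialyzer, slice,
#' threshold) count, the input format of [reproducibilityReport()].
#'
#' @param table1 data.frame as returned by [loadTable1Fixture()].
#' @param group "used", "blanco" or "all".
#' @return data.frame with columns dialyzer_id, slice_id,
#'   threshold_fraction, n_open.
#' @export
table1Counts <- function(table1 = loadTable1Fixture(),
                         group = c("all", "used", "blanco")) {
    group <- match.arg(group)
    if (group != "all") table1 <- table1[table1$group == group, ]
    long <- rbind(
        data.frame(dialyzer_id = table1$dialyzer_id, slice_id = "reference",
                   threshold_fraction = 0.70, n_open = table1$n_ref70),
        data.frame(dialyzer_id = table1$dialyzer_id,
                   slice_id = "offset_2.5mm",
                   threshold_fraction = 0.70, n_open = table1$n_offset70),
        data.frame(dialyzer_id = table1$dialyzer_id, slice_id = "reference",
                   threshold_fraction = 0.60, n_open = table1$n_ref60),
        data.frame(dialyzer_id = table1$dialyzer_id, slice_id = "reference",
                   threshold_fraction = 0.80, n_open = table1$n_ref80))
    long[order(match(long$dialyzer_id, table1$dialyzer_id)), ]
}
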