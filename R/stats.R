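# Downstream statistics on the factorial results table: normalization,
# non-parametric factor tests, linear fits with R^2.

#' Analyze one signal: indicators + HIC
#'
#' Runs the wavelet packet decomposition, the frequency-domain indicators
#' and the HIC on one acceleration trace and returns them as a one-row data
#' frame.
#'
#' @param signal An [accel_signal()].
#' @param levels Wavelet packet depth (default 9).
#' @param hic_window HIC window cap in seconds (default 0.015, HIC15).
#' @param filters A [qmf_pair()].
#' @return One-row data frame: `signal_label`, `e_max`, `band_index`,
#'   `f_low_hz`, `f_high_hz`, `proportion`, `total_energy`, `hic`.
#' @export
analyze_signal <- function(signal, levels = 9L, hic_window = 0.015,
                           filters = build_sym2()) {
  sp <- wp_decompose(signal, levels = levels, filters = filters)
  ind <- compute_indicators(sp)
  hic <- compute_hic(signal, max_window = hic_window)
  cbind(as.data.frame(ind),
        data.frame(total_energy = sp$total_energy, hic = hic$value))
}

#' Run the factorial simulation matrix and assemble the results table
#'
#' Simulates every scenario, analyzes each skull acceleration trace and
#' returns the assembled table (one row per scenario) fed to the
#' statistics stage.
#'
#' @param scenarios List of [impact_scenario()]s (see [generate_matrix()]).
#' @param head A [lumped_head_model()].
#' @param levels,hic_window,filters Passed to [analyze_signal()].
#' @return A data frame of class `factorial_result` with columns
#'   `scenario_id`, `position`, `material`, `velocity`, `size`, `e_max`,
#'   `band_index`, `f_low_hz`, `f_high_hz`, `proportion`, `total_energy`,
#'   `hic`.
#' @export
run_matrix <- function(scenarios, head = lumped_head_model(), levels = 9L,
                       hic_window = 0.015, filters = build_sym2()) {
  stopifnot(length(scenarios) >= 1L)
  rows <- lapply(scenarios, function(sc) {
    sig <- simulate_impact(sc, head)
    res <- analyze_signal(sig, levels = levels, hic_window = hic_window,
                          filters = filters)
    cbind(data.frame(scenario_id = sc$scenario_id, position = sc$position,
                     material = sc$material$name, velocity = sc$velocity,
                     size = sc$size, stringsAsFactors = FALSE),
          res[, setdiff(names(res), "signal_label")])
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$scenario_id))
    stop("run_matrix: duplicate scenario ids in the design")
  class(out) <- c("factorial_result", "data.frame")
  out
}

# response columns eligible for normalization / testing
.response_cols <- function(table) {
  intersect(c("e_max", "band_index", "proportion", "hic", "mps"),
            names(table))
}

#' Min-max normalize the response columns
#'
#' Rescales each response column to `[0, 1]` by `(x - min) / (max - min)`
#' (the scaling used for distribution plots across indicators of different
#' units). Z-scoring is available as an alternative. Constant columns are
#' rejected: they carry no information and the min-max map is undefined.
#'
#' @param table A `factorial_result` (or any data frame).
#' @param cols Columns to normalize; defaults to the recognised response
#'   columns present.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return The table with the named columns replaced by normalized values.
#' @export
normalize_responses <- function(table, cols = .response_cols(table),
                                method = c("minmax", "zscore")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table), length(cols) >= 1L)
  for (col in cols) {
    x <- table[[col]]
    if (!is.numeric(x)) stop("normalize_responses: '", col, "' not numeric")
    if (length(unique(x)) < 2L)
      stop("normalize_responses: constant column '", col, "'")
    table[[col]] <- if (method == "minmax") {
      (x - min(x)) / (max(x) - min(x))
    } else {
      (x - mean(x)) / stats::sd(x)
    }
  }
  table
}

#' Non-parametric factor test
#'
#' Kruskal-Wallis rank test of a response across the levels of one design
#' factor, pooling over all other factors (each level's group contains every
#' combination of the remaining factors). Ties are handled by mid-ranks with
#' the standard tie correction. Returns the raw p-value; no multiplicity
#' correction is applied across the factor x response grid (see
#' [factor_test_matrix()]).
#'
#' @param table A data frame.
#' @param factor Name of the grouping column (>= 2 levels, >= 2 observations
#'   per level).
#' @param response Name of the numeric response column.
#' @return The Kruskal-Wallis p-value.
#' @export
factor_test <- function(table, factor, response) {
  stopifnot(is.data.frame(table), factor %in% names(table),
            response %in% names(table))
  g <- as.factor(table[[factor]])
  y <- table[[response]]
  if (nlevels(droplevels(g)) < 2L)
    stop("factor_test: fewer than 2 groups in factor '", factor, "'")
  if (any(table(droplevels(g)) < 2L))
    stop("factor_test: a level of '", factor, "' has fewer than 2 observations")
  stats::kruskal.test(y, droplevels(g))$p.value
}

#' Factor-by-response matrix of non-parametric tests
#'
#' Runs [factor_test()] for every design factor against every response and
#' arranges the raw p-values as a factors-by-responses table with
#' significance stars at p < 0.05 (raw per-cell p-values, no
#' multiple-testing correction — flagged in the column name).
#'
#' @param table A `factorial_result`.
#' @param factors Factor column names (default the four design factors).
#' @param responses Response column names (default those present).
#' @return Data frame: `factor`, then one `p_<response>` and one
#'   `sig_<response>` column per response.
#' @export
factor_test_matrix <- function(table,
                               factors = c("position", "material",
                                           "velocity", "size"),
                               responses = .response_cols(table)) {
  stopifnot(all(factors %in% names(table)))
  out <- data.frame(factor = factors, stringsAsFactors = FALSE)
  for (resp in responses) {
    p <- vapply(factors, function(f) factor_test(table, f, resp), numeric(1))
    out[[paste0("p_", resp)]] <- p
    out[[paste0("sig_", resp)]] <- ifelse(p < 0.05, "*", "")
  }
  out
}

#' Ordinary least-squares line with R-squared
#'
#' Fits `y = intercept + slope * x` by OLS (via [stats::lm()]) and reports
#' the coefficient of determination `R^2 = 1 - SS_res / SS_tot`. A constant
#' `y` has `SS_tot = 0`; by convention the fit is returned with `r_squared =
#' 0` and a degenerate-fit warning rather than 0/0.
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must not be
#'   constant.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("linear_fit: fewer than 3 points")
  if (length(unique(x)) < 2L) stop("linear_fit: constant x")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("linear_fit: constant y (degenerate fit); r_squared set to 0")
    r2 <- 0
  } else {
    r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = length(x))
}

#' Linear fits of every frequency-domain indicator against a criterion
#'
#' Regresses each frequency-domain indicator (`e_max`, `band_index`,
#' `proportion`) on the chosen injury criterion column and tabulates slope,
#' intercept and R^2 — the correlation-structure summary of the pipeline.
#'
#' @param table A `factorial_result`.
#' @param criterion Criterion column (default `"hic"`; `"mps"` if joined).
#' @param indicators Indicator columns to fit.
#' @return Data frame: `indicator`, `criterion`, `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_indicators <- function(table, criterion = "hic",
                           indicators = c("e_max", "band_index",
                                          "proportion")) {
  stopifnot(criterion %in% names(table), all(indicators %in% names(table)))
  rows <- lapply(indicators, function(ind) {
    f <- linear_fit(table[[ind]], table[[criterion]])
    data.frame(indicator = ind, criterion = criterion, slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared, n = f$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
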