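#' Evaluation statistics for one model on one subset
#'
#' Computes the six standard agreement statistics between observed and
#' predicted values: Pearson correlation R, coefficient of determination R^2
#' (the squared correlation), RMSE, relative RMSE (RMSE as a percentage of the
#' observed mean), MAE, and MAPE. Following the source formulation, MAPE
#' divides each absolute error by the *predicted* value; the conventional
#' observed-value denominator is available via `mape_denominator`.
#'
#' If the observed or predicted values have zero variance the correlation is
#' undefined: R and R^2 are returned as `NA` with a warning. If any MAPE
#' denominator is zero, MAPE is returned as `NA` with a warning.
#'
#' @param observed,predicted Numeric vectors of equal length (n >= 2).
#' @param mape_denominator `"predicted"` (as printed in the source formula) or
#'   `"observed"` (the conventional form).
#' @return One-row data.frame with columns
#'   `rrmse_pct, rmse, mae, mape_pct, r2, r, n`.
#' @export
compute_metrics <- function(observed, predicted,
                            mape_denominator = c("predicted", "observed")) {
  mape_denominator <- match.arg(mape_denominator)
  n <- length(observed)
  if (n != length(predicted)) stop("observed and predicted must have equal length")
  if (n < 2) stop("need at least two observations")
  err <- observed - predicted
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  rrmse <- 100 * rmse / mean(observed)
  denom <- if (mape_denominator == "predicted") predicted else observed
  if (any(denom == 0)) {
    warning("zero ", mape_denominator, " value(s); MAPE undefined")
    mape <- NA_real_
  } else {
    mape <- 100 * mean(abs(err) / abs(denom))
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("zero-variance observed or predicted values; correlation undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(observed, predicted)
  }
  data.frame(rrmse_pct = rrmse, rmse = rmse, mae = mae, mape_pct = mape,
             r2 = r^2, r = r, n = n)
}

#' Full metric report for one fitted model
#'
#' @param model A fitted `surrogate` (labels are taken from it).
#' @param observed,predicted As in [compute_metrics()].
#' @param subset `"train"` or `"test"`.
#' @param ... Passed to [compute_metrics()].
#' @return One-row data.frame with identification columns prepended.
#' @export
metric_report <- function(model, observed, predicted, subset, ...) {
  cbind(data.frame(cultivar = model$cultivar %||% NA_character_,
                   model = model$kind,
                   trait = model$trait %||% NA_character_,
                   subset = subset),
        compute_metrics(observed, predicted, ...))
}

# indicator columns in GPI order, and their weights (-1: higher is better)
GPI_INDICATORS <- c("rrmse_pct", "rmse", "mae", "mape_pct", "r2", "r")
GPI_WEIGHTS <- c(rrmse_pct = 1, rmse = 1, mae = 1, mape_pct = 1, r2 = -1, r = -1)

#' Global Performance Indicator for a set of competing models
#'
#' Ranks models evaluated on the same data by a single number. Each indicator
#' column is min-max scaled to \[0, 1\] across the models; the median of the
#' scaled values (middle order statistic) is subtracted from each model's
#' scaled value; the differences are summed with weight -1 for R and R^2 and
#' +1 for the error indicators. Higher GPI is better. A degenerate indicator
#' (identical across models) contributes zero for every model and is flagged.
#'
#' @param reports Data.frame with one row per model: a `model` column plus the
#'   six indicator columns `rrmse_pct, rmse, mae, mape_pct, r2, r`.
#' @param expected_models Model identities that must each appear exactly once
#'   (set to `NULL` to skip the completeness check).
#' @return A `gpi_result`: `models`, `scaled_matrix`, `medians`, `weights`,
#'   `gpi` (named vector), `ranks` (1 = best), `degenerate` (flagged
#'   indicators), `tie` (whether ranking needed the lexicographic tie-break).
#' @export
compute_gpi <- function(reports, expected_models = MODEL_KINDS) {
  reports <- as.data.frame(reports)
  if (!is.null(expected_models)) {
    if (!setequal(reports$model, expected_models) ||
        nrow(reports) != length(expected_models)) {
      stop("need exactly one report per model: ",
           paste(expected_models, collapse = ", "))
    }
  }
  if (anyNA(reports[, GPI_INDICATORS])) stop("all six indicators must be present")
  m <- as.matrix(reports[, GPI_INDICATORS])
  rownames(m) <- reports$model
  degenerate <- character(0)
  S <- m
  for (j in colnames(m)) {
    rg <- max(m[, j]) - min(m[, j])
    if (rg == 0) {
      S[, j] <- 0
      degenerate <- c(degenerate, j)
    } else {
      S[, j] <- (m[, j] - min(m[, j])) / rg
    }
  }
  med <- apply(S, 2, stats::median)  # odd counts: middle order statistic
  gpi <- as.numeric(t(GPI_WEIGHTS[colnames(S)]) %*% (med - t(S)))
  names(gpi) <- rownames(m)
  ord <- order(-gpi, rownames(m))  # ties broken by model name
  ranks <- integer(length(gpi))
  ranks[ord] <- seq_along(gpi)
  names(ranks) <- rownames(m)
  structure(list(models = rownames(m), scaled_matrix = S, medians = med,
                 weights = GPI_WEIGHTS, gpi = gpi, ranks = ranks,
                 degenerate = degenerate,
                 tie = anyDuplicated(gpi) > 0),
            class = "gpi_result")
}

#' @export
print.gpi_result <- function(x, ...) {
  cat("Global Performance Indicator (higher is better)\n")
  out <- data.frame(model = x$models, gpi = round(x$gpi, 3), rank = x$ranks)
  print(out[order(out$rank), ], row.names = FALSE)
  if (length(x$degenerate)) {
    cat("degenerate indicator(s):", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize GPI rankings across cultivar-trait combinations
#'
#' @param gpi_tables Named list of `gpi_result` objects, one per
#'   (cultivar, trait) combination; names like `"Atabaki.LN"`.
#' @param expected_combos Character vector of combination names that must all
#'   be present (default: every cultivar x trait).
#' @return A list with `ranks` (data.frame of per-combination ranks) and
#'   `rank1_tally` (named count of rank-1 finishes per model).
#' @export
rank_models <- function(gpi_tables,
                        expected_combos = as.vector(outer(CULTIVARS, TRAITS,
                                                          paste, sep = "."))) {
  missing <- setdiff(expected_combos, names(gpi_tables))
  if (length(missing)) {
    stop("missing GPI result for combination(s): ", paste(missing, collapse = ", "))
  }
  ranks <- do.call(rbind, lapply(names(gpi_tables), function(nm) {
    g <- gpi_tables[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(cultivar = parts[1], trait = parts[2], model = g$models,
               gpi = as.numeric(g$gpi), rank = as.integer(g$ranks))
  }))
  winners <- ranks$model[ranks$rank == 1]
  tally <- table(factor(winners, levels = unique(ranks$model)))
  list(ranks = ranks, rank1_tally = c(tally))
}

#' Load the packaged per-model evaluation metric tables
#'
#' @return Data.frame of the printed per-model statistics for all cultivars,
#'   traits and subsets (the Shirineshahvar explant-survival training block is
#'   missing its stacking-ensemble row in the source and is packaged as
#'   printed).
#' @export
load_metric_fixtures <- function() {
  files <- c("table4_atabaki.csv", "table5_faroogh.csv", "table6_shirineshahvar.csv")
  do.call(rbind, lapply(files, function(f) {
    utils::read.csv(culturopt_extdata(f), stringsAsFactors = FALSE)
  }))
}

#' GPI for every cultivar-trait combination of a metrics table
#'
#' @param metrics Data.frame as returned by [load_metric_fixtures()] (or
#'   produced by the pipeline), with columns `cultivar, model, trait, subset`
#'   plus the six indicators.
#' @param subset Subset to rank on (the ranking is defined on the testing
#'   subset).
#' @return Named list of `gpi_result` objects (`"<cultivar>.<trait>"`).
#' @export
gpi_by_combination <- function(metrics, subset = "test") {
  metrics <- metrics[metrics$subset == subset, ]
  combos <- unique(metrics[, c("cultivar", "trait")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- metrics[metrics$cultivar == combos$cultivar[i] &
                   metrics$trait == combos$trait[i], ]
    compute_gpi(sub)
  })
  names(out) <- paste(combos$cultivar, combos$trait, sep = ".")
  out
}
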