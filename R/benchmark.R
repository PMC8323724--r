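# Mechanism x ratio benchmark harness: mask complete datasets, run each
# imputer, and score RMSE/NRMSE/MAE over the masked cells.

.scale01 <- function(x) {
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  rng <- ifelse(maxs > mins, maxs - mins, 1)
  sweep(sweep(x, 2L, mins), 2L, rng, "/")
}

.runMethod <- function(method, data, seed, k, c, config) {
  switch(method,
    mean = meanImpute(data),
    knni = knniImputeGlobal(data, k),
    ki = kiImpute(data, config = config, seed = seed),
    fcki = fckiImpute(data, config = config, c = c, seed = seed),
    .errSpec(sprintf("unknown method '%s'", method))
  )
}

#' Run the mechanism-by-ratio imputation benchmark
#'
#' For every dataset and every (mechanism, ratio) condition the harness
#' masks the complete dataset with a replicate-specific seed derived from
#' the master seed, runs each method on the masked copy, and scores the
#' result over exactly the masked cells. The default grid of 3 mechanisms
#' and 4 ratios gives 12 conditions per dataset per method.
#'
#' @param datasets a complete numeric matrix or a (preferably named) list of
#'   them.
#' @param methods character subset of `c("mean", "knni", "ki", "fcki")`.
#' @param ratios missing ratios in percent (default `c(1, 5, 10, 20)`).
#' @param mechanisms default all of MCAR, MAR, MNAR.
#' @param seed master seed; all condition seeds derive from it, so the table
#'   is bit-reproducible.
#' @param nAttrs attributes losing values for MAR/MNAR (capped at M).
#' @param k neighbour count for the global kNNI baseline.
#' @param c fixed FCKI cluster count, or `NULL` for the elbow rule.
#' @param config an [iterConfig()] for the regression stage.
#' @param scale01 min-max scale each column to `[0, 1]` before masking, so
#'   errors are comparable across features and datasets (on by default).
#' @param replicates masks per condition (default 1).
#' @return a tidy `data.frame` with one row per
#'   dataset/mechanism/ratio/method/replicate: the metrics, cell count and
#'   wall time.
#' @export
runBenchmark <- function(datasets, methods = c("mean", "knni", "ki", "fcki"),
                         ratios = c(1, 5, 10, 20),
                         mechanisms = c("MCAR", "MAR", "MNAR"),
                         seed = 1L, nAttrs = 2L, k = 5L, c = NULL,
                         config = iterConfig(), scale01 = TRUE,
                         replicates = 1L) {
  if (is.matrix(datasets)) datasets <- list(datasets)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  if (any(ratios <= 0 | ratios >= 100)) .errSpec("ratios must lie strictly in (0, 100)")
  rows <- list()
  for (di in seq_along(datasets)) {
    x <- .asDataset(datasets[[di]], names(datasets)[di])
    .checkComplete(x, names(datasets)[di])
    if (scale01) x <- .scale01(x)
    na_d <- as.integer(min(nAttrs, ncol(x)))
    for (mi in seq_along(mechanisms)) {
      for (ri in seq_along(ratios)) {
        for (rep in seq_len(replicates)) {
          maskSeed <- .deriveSeed(seed, di, mi, ri, rep)
          md <- generateMissing(x, mechanisms[mi], ratios[ri],
                                nAttrs = na_d, seed = maskSeed)
          for (method in methods) {
            t0 <- proc.time()[["elapsed"]]
            res <- .runMethod(method, maskedValues(md),
                              seed = .deriveSeed(maskSeed, match(method, methods)),
                              k = k, c = c, config = config)
            dt <- proc.time()[["elapsed"]] - t0
            rep_metrics <- evaluateMasked(truthValues(md), missingMask(md),
                                          imputedValues(res))
            rows[[length(rows) + 1L]] <- data.frame(
              dataset = names(datasets)[di],
              mechanism = mechanisms[mi],
              ratio = ratios[ri],
              method = method,
              replicate = rep,
              maskSeed = maskSeed,
              rmse = rep_metrics@rmse,
              nrmse = rep_metrics@nrmse,
              mae = rep_metrics@mae,
              nCells = rep_metrics@nCells,
              wallTime = dt,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate a benchmark table
#'
#' Averages the error metrics per method within the chosen grouping,
#' reproducing the usual report layouts: per dataset (mean over the 12
#' mechanism-by-ratio conditions, plus a final standard-deviation row of the
#' per-dataset means for each method), per mechanism, or per ratio.
#'
#' @param table a `data.frame` from [runBenchmark()].
#' @param by one of `"dataset"`, `"mechanism"`, `"ratio"`.
#' @param metric which metric column to aggregate.
#' @return a `data.frame` with one row per group, one column per method;
#'   for `by = "dataset"` an extra `"SD"` row holds the across-dataset
#'   standard deviation of the means.
#' @export
benchmarkSummary <- function(table, by = c("dataset", "mechanism", "ratio"),
                             metric = "rmse") {
  by <- match.arg(by)
  if (!metric %in% names(table)) .errSpec(sprintf("no metric column '%s'", metric))
  agg <- stats::aggregate(table[[metric]],
                          by = list(group = table[[by]], method = table$method),
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = "group", timevar = "method",
                         direction = "wide")
  names(wide) <- sub("^x\\.", "", names(wide))
  # keep first-appearance order of groups and methods
  wide <- wide[match(unique(table[[by]]), wide$group), , drop = FALSE]
  methods <- unique(table$method)
  wide <- wide[, c("group", methods), drop = FALSE]
  names(wide)[1L] <- by
  rownames(wide) <- NULL
  if (by == "dataset" && nrow(wide) > 1L) {
    sdRow <- c(list("SD"), lapply(methods, function(m) stats::sd(wide[[m]])))
    names(sdRow) <- names(wide)
    wide <- rbind(wide, as.data.frame(sdRow, stringsAsFactors = FALSE))
  }
  wide
}
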