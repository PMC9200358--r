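## Replicate aggregation: pointwise envelopes, pooled event statistics,
## dominance and affinity summaries. All functions here are pure — no RNG.

.checkResults <- function(results) {
  if (!length(results)) stop("no results supplied", call. = FALSE)
  if (!all(vapply(results, is, logical(1), "GCResult")))
    stop("expected a list of GCResult objects", call. = FALSE)
  ref <- .configAsList(results[[1]]@config)
  same <- vapply(results, function(r)
    identical(.configAsList(r@config), ref), logical(1))
  if (!all(same))
    stop("all results must share one configuration", call. = FALSE)
  invisible(results)
}

#' Aggregate replicate results
#'
#' Pointwise mean/min/max envelopes over replicates for every per-clone
#' series, pooled event-count summaries (mean and quartiles) for
#' centrocytes that reached the Tfh selection phase, and output-cell counts
#' per replicate.
#'
#' @param results list of [GCResult-class] objects sharing one
#'   configuration.
#' @return a [GCSummary-class].
#' @examples
#' \donttest{
#' reps <- runReplicates(smallGCConfig(scenario = 0, nReplicates = 2))
#' aggregateReplicates(reps)
#' }
#' @export
aggregateReplicates <- function(results) {
  .checkResults(results)
  seriesCols <- c("n_cb", "n_cc", "n_oc_cum", "ag_collected_total",
                  "mean_affinity_alive", "mean_affinity_oc_cum")
  ts1 <- timeSeries(results[[1]])
  key <- paste(ts1$clone_id, ts1$time_h)
  stats <- do.call(rbind, lapply(seriesCols, function(col) {
    mat <- vapply(results, function(r) timeSeries(r)[[col]],
                  numeric(nrow(ts1)))
    mat <- matrix(mat, nrow = nrow(ts1))
    data.frame(clone_id = ts1$clone_id, time_h = ts1$time_h, series = col,
               mean = rowMeans(mat, na.rm = TRUE),
               min = suppressWarnings(apply(mat, 1, min, na.rm = TRUE)),
               max = suppressWarnings(apply(mat, 1, max, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  stats$mean[is.nan(stats$mean)] <- NA_real_
  stats$min[!is.finite(stats$min)] <- NA_real_
  stats$max[!is.finite(stats$max)] <- NA_real_

  ev <- do.call(rbind, lapply(results, cellEvents))
  evCols <- c("n_fdc_contacts", "n_associations", "n_dissoc_no_ag",
              "n_dissoc_with_ag")
  eventStats <- if (nrow(ev)) {
    do.call(rbind, lapply(split(ev, ev$clone_id), function(d) {
      do.call(rbind, lapply(evCols, function(col) {
        q <- quantile(d[[col]], c(0.25, 0.5, 0.75))
        data.frame(clone_id = d$clone_id[1], event = col,
                   n_cells = nrow(d), mean = mean(d[[col]]),
                   q25 = q[[1]], median = q[[2]], q75 = q[[3]],
                   stringsAsFactors = FALSE)
      }))
    }))
  } else data.frame(clone_id = character(), event = character(),
                    n_cells = integer(), mean = numeric(), q25 = numeric(),
                    median = numeric(), q75 = numeric())
  rownames(eventStats) <- NULL

  ocCounts <- do.call(rbind, lapply(seq_along(results), function(i) {
    cl <- cloneTable(results[[i]])$cloneId
    log <- ocLog(results[[i]])
    data.frame(replicate = i, clone_id = cl,
               n_oc = vapply(cl, function(x) sum(log$clone_id == x),
                             numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(ocCounts) <- NULL

  new("GCSummary", timeSeriesStats = stats, eventStats = eventStats,
      ocCounts = ocCounts, nReplicates = length(results))
}

#' Per-replicate daily dominance report
#'
#' For each replicate and simulated day, the clone with the strictly
#' largest CB+CC population at the daily sample; exact ties are reported as
#' ties (`dominant` is `NA`).
#'
#' @param results list of [GCResult-class] objects.
#' @return data.frame with `replicate`, `day`, `dominant`, `tie`.
#' @examples
#' \donttest{
#' reps <- runReplicates(smallGCConfig(scenario = 1, nReplicates = 2))
#' dominanceReport(reps)
#' }
#' @export
dominanceReport <- function(results) {
  .checkResults(results)
  do.call(rbind, lapply(seq_along(results), function(i) {
    ts <- timeSeries(results[[i]])
    ts <- ts[ts$time_h %% 24 == 0 & ts$time_h > 0, ]
    if (!nrow(ts)) return(NULL)
    do.call(rbind, lapply(split(ts, ts$time_h), function(d) {
      tot <- d$n_cb + d$n_cc
      top <- which(tot == max(tot))
      tie <- length(top) > 1L
      data.frame(replicate = i, day = d$time_h[1] / 24,
                 dominant = if (tie) NA_character_ else d$clone_id[top],
                 tie = tie, stringsAsFactors = FALSE)
    }))
  }))
}

#' Affinity-maturation curves
#'
#' Living-cell mean affinity (computed over currently alive cells of each
#' clone; missing when a clone is extinct) and the cumulative mean affinity
#' of output cells produced since t = 0 (output cells never die, so this
#' running mean is over all of them), averaged over replicates.
#'
#' @param results list of [GCResult-class] objects.
#' @return data.frame with `clone_id`, `time_h`, `mean_affinity_alive`,
#'   `mean_affinity_oc_cum` (replicate means, NA where undefined in every
#'   replicate).
#' @examples
#' \donttest{
#' reps <- runReplicates(smallGCConfig(scenario = 1, nReplicates = 2))
#' tail(affinityCurves(reps))
#' }
#' @export
affinityCurves <- function(results) {
  .checkResults(results)
  ts1 <- timeSeries(results[[1]])
  alive <- vapply(results, function(r) timeSeries(r)$mean_affinity_alive,
                  numeric(nrow(ts1)))
  occ <- vapply(results, function(r) timeSeries(r)$mean_affinity_oc_cum,
                numeric(nrow(ts1)))
  alive <- matrix(alive, nrow = nrow(ts1))
  occ <- matrix(occ, nrow = nrow(ts1))
  out <- data.frame(clone_id = ts1$clone_id, time_h = ts1$time_h,
                    mean_affinity_alive = rowMeans(alive, na.rm = TRUE),
                    mean_affinity_oc_cum = rowMeans(occ, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  out$mean_affinity_alive[is.nan(out$mean_affinity_alive)] <- NA_real_
  out$mean_affinity_oc_cum[is.nan(out$mean_affinity_oc_cum)] <- NA_real_
  out
}
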