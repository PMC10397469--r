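#' Summarise MID estimates across methods and anchors
#'
#' For each metric x direction x scale cell, each method's estimates are first
#' averaged over anchors (simple average), and the summary then reports the
#' mean of those method-level means together with their min-max range -- the
#' "mean and range of means across methods" reporting shape. The method-level
#' means themselves are recoverable from [heatmap_table()], so either
#' aggregation reading can be reconstructed. Relative-scale values are
#' reported as percentages of baseline. Only `status == "ok"` rows
#' contribute; empty cells are omitted with a message.
#'
#' @param mids Long MID table from [estimate_all()].
#' @return Data frame with columns `metric`, `units`, `direction`, `scale`,
#'   `mean_mid`, `min_mid`, `max_mid`, `n_methods`, `methods_included`,
#'   `anchors_included`.
#' @export
summarize_mids <- function(mids) {
  ok <- mids[!is.na(mids$status) & mids$status == "ok" &
               is.finite(mids$value), , drop = FALSE]
  if (!nrow(ok)) stop("no usable MID estimates to summarise")
  ok$value_rep <- ifelse(ok$scale == "relative", ok$value * 100, ok$value)
  ok$units_rep <- ifelse(ok$scale == "relative", "% of baseline", ok$units)

  cells <- unique(ok[, c("metric", "direction", "scale")])
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- ok[ok$metric == cells$metric[i] &
                ok$direction == cells$direction[i] &
                ok$scale == cells$scale[i], , drop = FALSE]
    method_means <- tapply(sub$value_rep, sub$method, mean)
    method_means <- method_means[!is.na(method_means)]
    if (!length(method_means)) {
      message("summarize_mids: no estimates for ", cells$metric[i], " / ",
              cells$direction[i], " / ", cells$scale[i], "; cell omitted")
      next
    }
    ord <- intersect(.mid_methods, names(method_means))
    method_means <- method_means[ord]
    rows[[i]] <- data.frame(
      metric = cells$metric[i], units = sub$units_rep[1],
      direction = cells$direction[i], scale = cells$scale[i],
      mean_mid = mean(method_means),
      min_mid = min(method_means), max_mid = max(method_means),
      n_methods = length(method_means),
      methods_included = paste(ord, collapse = ","),
      anchors_included = paste(sort(unique(sub$anchor)), collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$metric, out$scale, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Methods x metrics table of mean MIDs
#'
#' The per-method, per-metric mean MID (averaged over anchors) for one
#' direction and scale, arranged as a plain matrix-shaped data frame in the
#' fixed method order `half_sd`, `mdc`, `change_difference`,
#' `glm_regression`, with an `average` row and column appended. This is the
#' tabular counterpart of a heatmap of MIDs; write it with
#' [utils::write.csv()] or pass it to any plotting front-end.
#'
#' @param mids Long MID table from [estimate_all()].
#' @param direction `"improvement"` or `"worsening"`.
#' @param scale `"absolute"` or `"relative"`.
#' @return Data frame with methods (plus `average`) as rows and metrics
#'   (plus `average`) as columns.
#' @export
heatmap_table <- function(mids, direction = c("improvement", "worsening"),
                          scale = c("absolute", "relative")) {
  direction <- match.arg(direction)
  scale <- match.arg(scale)
  ok <- mids[!is.na(mids$status) & mids$status == "ok" &
               is.finite(mids$value) & mids$direction == direction &
               mids$scale == scale, , drop = FALSE]
  if (!nrow(ok)) {
    stop("no usable MID estimates for direction '", direction,
         "', scale '", scale, "'")
  }
  metrics <- unique(ok$metric)
  mat <- matrix(NA_real_, nrow = length(.mid_methods),
                ncol = length(metrics),
                dimnames = list(.mid_methods, metrics))
  for (me in .mid_methods) {
    for (mm in metrics) {
      v <- ok$value[ok$method == me & ok$metric == mm]
      if (length(v)) mat[me, mm] <- mean(v)
    }
  }
  mat <- rbind(mat, average = colMeans(mat, na.rm = TRUE))
  mat <- cbind(mat, average = rowMeans(mat, na.rm = TRUE))
  as.data.frame(mat)
}
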