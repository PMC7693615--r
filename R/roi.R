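#' Pool channel summaries to ROI activations
#'
#' Pools per-channel scalar HBdiff summaries over the montage hierarchy:
#' channels -> sub-ROI (DLPFC/VLPFC/IPL/SPL x hemisphere, unweighted channel
#' mean) -> region x hemisphere (mean of the two sub-ROI means) ->
#' hemisphere (mean of the two region means). QC- or outlier-dropped
#' channels enter as `NA` and are dropped from the mean; a cell with no
#' surviving channel is reported missing (`NA`, `n_channels_used = 0`).
#'
#' @param values named numeric vector of per-channel summaries; names are
#'   channel labels matching `mapping$label`. `NA` = dropped channel.
#' @param mapping channel table from [map_channels_to_rois()]
#' @param level pooling level to return
#' @return data.frame with `roi`/`region`/`hemisphere` (as applicable),
#'   `hbdiff_mean` and `n_channels_used`
#' @export
pool_roi <- function(values, mapping, level = c("region", "subroi", "hemisphere")) {
  level <- match.arg(level)
  mapping$value <- values[mapping$label]
  sub <- do.call(rbind, lapply(split(mapping, list(mapping$roi, mapping$hemisphere),
                                     drop = TRUE), function(g) {
    data.frame(roi = g$roi[1], region = g$region[1], hemisphere = g$hemisphere[1],
               hbdiff_mean = if (all(is.na(g$value))) NA_real_
                             else mean(g$value, na.rm = TRUE),
               n_channels_used = sum(!is.na(g$value)),
               stringsAsFactors = FALSE)
  }))
  rownames(sub) <- NULL
  if (level == "subroi") return(sub)
  reg <- do.call(rbind, lapply(split(sub, list(sub$region, sub$hemisphere),
                                     drop = TRUE), function(g) {
    ok <- !is.na(g$hbdiff_mean)
    data.frame(region = g$region[1], hemisphere = g$hemisphere[1],
               hbdiff_mean = if (!any(ok)) NA_real_ else mean(g$hbdiff_mean[ok]),
               n_channels_used = sum(g$n_channels_used),
               stringsAsFactors = FALSE)
  }))
  rownames(reg) <- NULL
  if (level == "region") return(reg)
  hemi <- do.call(rbind, lapply(split(reg, reg$hemisphere, drop = TRUE),
                                function(g) {
    ok <- !is.na(g$hbdiff_mean)
    data.frame(hemisphere = g$hemisphere[1],
               hbdiff_mean = if (!any(ok)) NA_real_ else mean(g$hbdiff_mean[ok]),
               n_channels_used = sum(g$n_channels_used),
               stringsAsFactors = FALSE)
  }))
  rownames(hemi) <- NULL
  hemi
}

#' Pairwise correlations between ROI activation summaries
#'
#' Pearson correlations (with two-sided p-values) between ROI columns
#' across observations (participant x time point rows). Used to justify
#' pooling sub-ROIs into regions.
#'
#' @param activations data.frame or matrix; columns = ROI summaries, rows =
#'   observations. Non-numeric columns are ignored.
#' @return data.frame with `roi1`, `roi2`, `n`, `r`, `p`
#' @export
roi_correlations <- function(activations) {
  x <- as.data.frame(activations)
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  cols <- names(x)
  rows <- list()
  for (i in seq_along(cols)) {
    for (j in seq_along(cols)) {
      if (j <= i) next
      ok <- stats::complete.cases(x[[i]], x[[j]])
      if (sum(ok) < 3)
        stop("roi_correlations: fewer than 3 complete pairs for ",
             cols[i], " vs ", cols[j], call. = FALSE)
      ct <- stats::cor.test(x[[i]][ok], x[[j]][ok])
      rows[[length(rows) + 1]] <- data.frame(
        roi1 = cols[i], roi2 = cols[j], n = sum(ok),
        r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
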