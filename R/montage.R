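#' Default fronto-parietal montage
#'
#' Returns the 38-channel montage used by the simulator and the ROI mapping:
#' 18 channels over bilateral dorsolateral and ventrolateral prefrontal
#' cortex (DLPFC, VLPFC), 14 channels over bilateral inferior and superior
#' parietal lobes (IPL, SPL), and 6 channels outside the fronto-parietal
#' network that are excluded from analysis. ROI assignments follow the
#' published channel numbering; the source/detector indices for the
#' non-excluded channels are synthetic (generated pairings consistent with a
#' 16-source/16-detector layout), as only the excluded channels' optode
#' pairs are documented.
#'
#' @param distance source-detector separation in metres (0.03 default)
#' @return data.frame with columns `channel`, `source`, `detector`,
#'   `label` (10-20 style), `hemisphere` (`"left"`/`"right"`),
#'   `roi` (`"DLPFC"`, `"VLPFC"`, `"IPL"`, `"SPL"`, `"excluded"`) and
#'   `distance` (metres)
#' @export
default_montage <- function(distance = 0.03) {
  roi <- character(38)
  hemi <- character(38)
  assign_roi <- function(ch, r, h) {
    roi[ch] <<- r
    hemi[ch] <<- h
  }
  assign_roi(1:4, "DLPFC", "left")
  assign_roi(c(14, 15, 17, 18), "DLPFC", "right")
  assign_roi(5:9, "VLPFC", "left")
  assign_roi(c(10:13, 16), "VLPFC", "right")
  assign_roi(c(19, 21:23, 25), "IPL", "left")
  assign_roi(c(29, 31:33, 35), "IPL", "right")
  assign_roi(c(20, 24), "SPL", "left")
  assign_roi(c(30, 34), "SPL", "right")
  assign_roi(c(26:28), "excluded", "left")
  assign_roi(c(36:38), "excluded", "right")

  # synthetic optode pairing: two channels per source, detectors interleaved;
  # the six excluded channels carry their documented pairs
  src <- ceiling(seq_len(38) / 2.5)
  det <- pmin(16, src + (seq_len(38) %% 2))
  src[26:28] <- c(11, 12, 12); det[26:28] <- c(12, 11, 12)
  src[36:38] <- c(15, 16, 16); det[36:38] <- c(16, 15, 16)

  data.frame(
    channel = seq_len(38),
    source = paste0("S", src),
    detector = paste0("D", det),
    label = paste0("CH", seq_len(38)),
    hemisphere = hemi,
    roi = roi,
    distance = distance,
    stringsAsFactors = FALSE
  )
}

#' Map channels to analysis regions
#'
#' Drops channels marked `excluded` and attaches the region grouping used
#' for pooling: DLPFC and VLPFC channels belong to the `frontal` region,
#' IPL and SPL channels to the `parietal` region.
#'
#' @param montage a montage data.frame (see [default_montage()])
#' @return data.frame of retained channels with added `region` column
#' @export
map_channels_to_rois <- function(montage) {
  if (nrow(montage) == 0) return(cbind(montage, region = character(0)))
  known <- c("DLPFC", "VLPFC", "IPL", "SPL", "excluded")
  bad <- setdiff(unique(montage$roi), known)
  if (length(bad) > 0)
    stop("map_channels_to_rois: unknown ROI label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  kept <- montage[montage$roi != "excluded", , drop = FALSE]
  kept$region <- ifelse(kept$roi %in% c("DLPFC", "VLPFC"), "frontal", "parietal")
  rownames(kept) <- NULL
  kept
}

#' Read / write a montage as a delimited file
#'
#' @param montage montage data.frame
#' @param path file path (tab-separated)
#' @return `read_montage` returns the montage data.frame
#' @export
write_montage <- function(montage, path) {
  utils::write.table(montage, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("channel", "source", "detector", "hemisphere", "roi", "distance")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0)
    stop("read_montage: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m
}
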