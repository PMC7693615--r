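# Constructors for minimal pipeline objects used across tests.

# wrap a samples x channels matrix (same series at both wavelengths unless
# od2 given) into an od_series
make_od <- function(od1, od2 = od1, fs = 3.47, events = NULL, age = 69,
                    montage = NULL) {
  od1 <- as.matrix(od1)
  nch <- ncol(od1)
  if (is.null(montage)) {
    montage <- data.frame(channel = seq_len(nch), source = "S1",
                          detector = "D1", label = paste0("CH", seq_len(nch)),
                          hemisphere = "left", roi = "DLPFC", distance = 0.03,
                          stringsAsFactors = FALSE)
  }
  arr <- array(NA_real_, dim = c(nrow(od1), nch, 2))
  arr[, , 1] <- od1
  arr[, , 2] <- od2
  structure(list(od = arr, fs = fs, time = (seq_len(nrow(od1)) - 1) / fs,
                 wavelengths = c(760, 850), events = events, montage = montage,
                 age = age, qc_passed = NULL, motion_corrected = FALSE,
                 filtered = FALSE),
            class = "od_series")
}

# wrap concentration matrices into an hb_series
make_hb <- function(hbo, hhb = hbo * 0, fs = 3.47, events = NULL) {
  hbo <- as.matrix(hbo)
  nch <- ncol(hbo)
  montage <- data.frame(channel = seq_len(nch), label = paste0("CH", seq_len(nch)),
                        hemisphere = "left", roi = "DLPFC", distance = 0.03,
                        stringsAsFactors = FALSE)
  colnames(hbo) <- montage$label
  structure(list(hbo = hbo, hhb = as.matrix(hhb), hbt = hbo + hhb,
                 hbdiff = hbo - hhb, fs = fs,
                 time = (seq_len(nrow(hbo)) - 1) / fs,
                 events = events, montage = montage, qc_passed = NULL),
            class = "hb_series")
}

# small deterministic trial table: one participant/condition/time point,
# 2 blocks x 15 trials with given correctness and RT patterns
make_trials <- function(correct, rt, condition = "2-back", time_point = "pre",
                        participant_id = "P1") {
  n <- 30
  stopifnot(length(correct) == n, length(rt) == n)
  data.frame(
    participant_id = participant_id, time_point = time_point,
    condition = condition, block = rep(1:2, each = 15), trial = rep(1:15, 2),
    onset = seq(0, by = 3, length.out = n),
    is_target = rep(c(rep(FALSE, 10), rep(TRUE, 5)), 2),
    response = ifelse(is.na(rt), "none", "match"),
    rt = rt, correct = correct & !is.na(rt),
    stringsAsFactors = FALSE
  )
}
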