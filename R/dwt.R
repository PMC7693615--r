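# Periodized Daubechies-2 discrete wavelet transform.
#
# The analysis step is a periodic correlation with the orthonormal db2
# filter pair; for even lengths the transform is orthonormal, so the
# synthesis step is its adjoint and reconstruction is exact to machine
# precision. Odd lengths are handled by repeating the final sample (the
# extra sample is dropped on reconstruction), so output length always
# equals input length.

.db2_lo <- c(0.48296291314453416, 0.83651630373780790,
             0.22414386804201340, -0.12940952255126037)
.db2_hi <- c(-0.12940952255126037, -0.22414386804201340,
             0.83651630373780790, -0.48296291314453416)

# one analysis level on an even-length vector; returns list(cA, cD)
dwt_step <- function(x) {
  n <- length(x)
  k <- seq_len(n / 2)
  pos0 <- 2 * (k - 1) - 1 # 0-based start of each 4-tap window
  cA <- numeric(n / 2)
  cD <- numeric(n / 2)
  for (j in 0:3) {
    idx <- (pos0 + j) %% n + 1
    cA <- cA + .db2_lo[j + 1] * x[idx]
    cD <- cD + .db2_hi[j + 1] * x[idx]
  }
  list(cA = cA, cD = cD)
}

# adjoint of dwt_step (exact inverse for even lengths)
idwt_step <- function(cA, cD) {
  n <- 2 * length(cA)
  x <- numeric(n)
  k <- seq_along(cA)
  pos0 <- 2 * (k - 1) - 1
  for (j in 0:3) {
    idx <- (pos0 + j) %% n + 1
    contrib <- .db2_lo[j + 1] * cA + .db2_hi[j + 1] * cD
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Multi-level db2 wavelet decomposition
#'
#' @param x numeric vector
#' @param levels decomposition depth; capped at `floor(log2(length(x))) - 1`
#' @return list with `approx` (coarsest approximation), `details` (list of
#'   detail coefficient vectors, finest first) and `n` (original length)
#' @export
dwt_db2 <- function(x, levels) {
  n0 <- length(x)
  if (n0 < 4) stop("dwt_db2: series too short", call. = FALSE)
  levels <- min(levels, floor(log2(n0)) - 1)
  details <- vector("list", levels)
  odd <- logical(levels)
  cur <- x
  for (l in seq_len(levels)) {
    odd[l] <- length(cur) %% 2 == 1
    if (odd[l]) cur <- c(cur, cur[length(cur)])
    s <- dwt_step(cur)
    details[[l]] <- s$cD
    cur <- s$cA
  }
  structure(list(approx = cur, details = details, odd = odd, n = n0),
            class = "dwt_db2")
}

#' Inverse multi-level db2 wavelet transform
#'
#' @param w decomposition from [dwt_db2()]
#' @return numeric vector of the original length
#' @export
idwt_db2 <- function(w) {
  cur <- w$approx
  for (l in rev(seq_along(w$details))) {
    cur <- idwt_step(cur, w$details[[l]])
    if (w$odd[l]) cur <- cur[-length(cur)]
  }
  cur[seq_len(w$n)]
}
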