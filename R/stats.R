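#' Greenhouse-Geisser epsilon from a within-level covariance matrix
#'
#' Box's sphericity correction factor computed from the k x k covariance
#' matrix of the within-subject level measures via the double-centered
#' formula; clamped to its theoretical range `[1/(k-1), 1]`. Under compound
#' symmetry (sphericity) the value is exactly 1.
#'
#' @param S symmetric positive semi-definite covariance matrix (k >= 2)
#' @return epsilon in `[1/(k-1), 1]`
#' @export
gg_epsilon <- function(S) {
  S <- as.matrix(S)
  k <- nrow(S)
  stopifnot(k >= 2, ncol(S) == k)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("gg_epsilon: covariance matrix must be symmetric", call. = FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("gg_epsilon: covariance matrix must be positive semi-definite",
         call. = FALSE)
  # double centering projects out the level means
  Sc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  num <- sum(diag(Sc))^2
  den <- (k - 1) * sum(Sc^2)
  if (den <= 0) return(1)
  max(1 / (k - 1), min(1, num / den))
}

# orthonormal Helmert-style contrasts, (k-1) x k
.ortho_contrasts <- function(k) {
  C <- t(stats::contr.helmert(k))
  C / sqrt(rowSums(C^2))
}

# Mauchly's sphericity test on the d x d contrast-space covariance,
# with the standard chi-square approximation
.mauchly <- function(St, n_error) {
  d <- nrow(St)
  if (d < 2) return(list(W = NA_real_, p = NA_real_))
  ev <- eigen(St, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(list(W = 0, p = 0))
  W <- prod(ev) / (mean(ev)^d)
  f <- (2 * d^2 + d + 2) / (6 * d * n_error)
  chi2 <- -(1 - f) * n_error * log(W)
  df <- d * (d + 1) / 2 - 1
  list(W = W, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Mixed repeated-measures ANOVA
#'
#' Fits a fully crossed design with one between-subjects factor and up to
#' three within-subjects factors (subjects nested in the between factor as
#' error strata), on balanced complete cases. Sums of squares are
#' partitioned through the classical univariate strata decomposition; each
#' effect is tested against its matching error stratum. For every within
#' effect, the Greenhouse-Geisser epsilon is estimated from the pooled
#' within-group covariance of the orthonormal contrast scores and used to
#' produce corrected p-values; Mauchly's sphericity test is reported
#' alongside. Effect sizes are generalized eta squared: the effect sum of
#' squares over itself plus all error sums of squares.
#'
#' @param data long-format data.frame
#' @param dv name of the response column
#' @param subject name of the subject identifier column
#' @param between name of the between-subjects factor (or `NULL`)
#' @param within character vector of within-subjects factor names (1-3)
#' @return data.frame of class `anova_result`: per effect `df_num`,
#'   `df_den`, `SS`, `SS_err`, `F`, `p`, `epsilon`, `df_num_gg`, `df_den_gg`,
#'   `p_gg`, `ges`, `mauchly_W`, `mauchly_p`; attribute `n_subjects` and
#'   `n_dropped` (listwise-deleted incomplete subjects)
#' @export
mixed_rm_anova <- function(data, dv, subject, between = NULL, within) {
  stopifnot(length(within) >= 1, length(within) <= 3)
  d <- data
  d[[subject]] <- factor(d[[subject]])
  for (f in c(between, within)) d[[f]] <- factor(d[[f]])
  d <- d[stats::complete.cases(d[, c(dv, subject, between, within)]), ]

  # listwise deletion: keep subjects observed in every within cell
  n_cells <- prod(vapply(within, function(f) nlevels(d[[f]]), integer(1)))
  cnt <- table(d[[subject]])
  keep <- names(cnt)[cnt == n_cells]
  n_dropped <- sum(cnt != n_cells)
  if (n_dropped > 0)
    message("mixed_rm_anova: dropped ", n_dropped,
            " subject(s) with incomplete cells")
  d <- d[d[[subject]] %in% keep, ]
  d[[subject]] <- droplevels(d[[subject]])
  n_subj <- nlevels(d[[subject]])
  if (n_subj < 3) stop("mixed_rm_anova: fewer than 3 complete subjects",
                       call. = FALSE)

  fixed <- paste(c(between, within), collapse = " * ")
  err <- paste(within, collapse = " * ")
  fml <- stats::as.formula(sprintf("%s ~ %s + Error(%s/(%s))",
                                   dv, fixed, subject, err))
  fit <- stats::aov(fml, data = d)
  sm <- summary(fit)

  # harvest all effect and residual rows from the strata
  rows <- list()
  total_err_ss <- 0
  for (stratum in sm) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    nm <- trimws(rownames(tab))
    res <- nm == "Residuals"
    ss_err <- if (any(res)) tab[res, "Sum Sq"] else NA_real_
    df_err <- if (any(res)) tab[res, "Df"] else NA_real_
    total_err_ss <- total_err_ss + ifelse(is.na(ss_err), 0, ss_err)
    for (i in which(!res)) {
      rows[[length(rows) + 1]] <- data.frame(
        effect = gsub(":", ":", nm[i]), SS = tab[i, "Sum Sq"],
        df_num = tab[i, "Df"], SS_err = ss_err, df_den = df_err,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)

  # wide subject x within-cell matrix for epsilon/Mauchly, first within
  # factor varying fastest (matching the Kronecker ordering below)
  grid <- expand.grid(lapply(within, function(f) levels(d[[f]])),
                      stringsAsFactors = FALSE)
  names(grid) <- within
  cell_of <- interaction(d[, within, drop = FALSE], drop = FALSE, lex.order = FALSE)
  key <- interaction(grid, drop = FALSE, lex.order = FALSE)
  Y <- matrix(NA_real_, n_subj, nrow(grid),
              dimnames = list(levels(d[[subject]]), as.character(key)))
  for (i in seq_len(nrow(d)))
    Y[as.character(d[[subject]][i]), as.character(cell_of[i])] <- d[[dv]][i]
  if (any(is.na(Y)))
    stop("mixed_rm_anova: unbalanced within-cell structure after deletion",
         call. = FALSE)
  grp <- if (is.null(between)) {
    factor(rep("all", n_subj))
  } else {
    g <- d[[between]][match(rownames(Y), as.character(d[[subject]]))]
    droplevels(g)
  }
  centred <- Y
  for (lv in levels(grp))
    centred[grp == lv, ] <- scale(Y[grp == lv, , drop = FALSE],
                                  center = TRUE, scale = FALSE)
  S <- crossprod(centred) / (n_subj - nlevels(grp))

  # epsilon per within-factor subset, from the contrast-space covariance
  eps_of <- list()
  mauchly_of <- list()
  subsets <- unlist(lapply(seq_along(within), function(m)
    utils::combn(within, m, simplify = FALSE)), recursive = FALSE)
  for (sub in subsets) {
    M <- matrix(1, 1, 1)
    for (f in rev(within)) { # leftmost kron factor = slowest-varying
      k <- nlevels(d[[f]])
      Mf <- if (f %in% sub) .ortho_contrasts(k) else matrix(1 / k, 1, k)
      M <- M %x% Mf
    }
    St <- M %*% S %*% t(M)
    key <- paste(sort(sub), collapse = ":")
    eps_of[[key]] <- gg_epsilon_contrast(St)
    mauchly_of[[key]] <- .mauchly(St, n_subj - nlevels(grp))
  }

  out$epsilon <- 1
  out$mauchly_W <- NA_real_
  out$mauchly_p <- NA_real_
  for (i in seq_len(nrow(out))) {
    parts <- strsplit(out$effect[i], ":", fixed = TRUE)[[1]]
    wpart <- sort(intersect(parts, within))
    if (length(wpart) > 0) {
      key <- paste(wpart, collapse = ":")
      out$epsilon[i] <- eps_of[[key]]
      out$mauchly_W[i] <- mauchly_of[[key]]$W
      out$mauchly_p[i] <- mauchly_of[[key]]$p
    }
  }

  out$F <- out$SS / out$df_num / (out$SS_err / out$df_den)
  out$p <- stats::pf(out$F, out$df_num, out$df_den, lower.tail = FALSE)
  out$df_num_gg <- out$df_num * out$epsilon
  out$df_den_gg <- out$df_den * out$epsilon
  out$p_gg <- stats::pf(out$F, out$df_num_gg, out$df_den_gg, lower.tail = FALSE)
  out$ges <- out$SS / (out$SS + total_err_ss)
  out$degenerate <- out$SS_err <= 1e-12 * max(out$SS, 1e-300)
  rownames(out) <- NULL
  attr(out, "n_subjects") <- n_subj
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("anova_result", "data.frame")
  out
}

# Box epsilon directly from a contrast-space covariance (already projected)
gg_epsilon_contrast <- function(St) {
  d <- nrow(St)
  if (d < 2) return(1)
  num <- sum(diag(St))^2
  den <- d * sum(St^2)
  if (den <= 0) return(1)
  max(1 / d, min(1, num / den))
}

#' Planned contrasts against the pretest
#'
#' Within each group, paired comparisons of each follow-up time point
#' against the pretest, Bonferroni-corrected over the per-group family.
#'
#' @param data long data.frame with one row per subject x time point
#' @param dv,subject,group,time column names
#' @param reference reference (pretest) level of `time`
#' @param family_size Bonferroni family size; default = number of contrasts
#'   per group
#' @return data.frame: `group`, `contrast`, `n`, `estimate`, `se`, `t`,
#'   `df`, `p`, `p_adj`, `degenerate`
#' @export
planned_contrasts <- function(data, dv, subject, group, time,
                              reference = "pre", family_size = NULL) {
  d <- data
  d[[time]] <- factor(d[[time]])
  stopifnot(reference %in% levels(d[[time]]))
  followups <- setdiff(levels(d[[time]]), reference)
  m <- if (is.null(family_size)) length(followups) else family_size
  rows <- list()
  for (g in unique(d[[group]])) {
    dg <- d[d[[group]] == g, ]
    ref <- dg[dg[[time]] == reference, c(subject, dv)]
    for (tp in followups) {
      fol <- dg[dg[[time]] == tp, c(subject, dv)]
      mrg <- merge(ref, fol, by = subject, suffixes = c(".ref", ".fol"))
      mrg <- mrg[stats::complete.cases(mrg), ]
      n <- nrow(mrg)
      if (n < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          group = g, contrast = paste(reference, "vs", tp), n = n,
          estimate = NA_real_, se = NA_real_, t = NA_real_, df = NA_real_,
          p = NA_real_, p_adj = NA_real_, degenerate = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      diffs <- mrg[[paste0(dv, ".fol")]] - mrg[[paste0(dv, ".ref")]]
      est <- mean(diffs)
      se <- stats::sd(diffs) / sqrt(n)
      zero_se <- se <= 1e-10 * max(abs(est), 1e-300) # exact shift up to rounding
      degenerate <- zero_se && est != 0
      tval <- if (zero_se) {
        if (est == 0) 0 else sign(est) * Inf
      } else {
        est / se
      }
      p <- if (is.infinite(tval)) 0
           else 2 * stats::pt(-abs(tval), n - 1)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, contrast = paste(reference, "vs", tp), n = n,
        estimate = est, se = se, t = tval, df = n - 1, p = p,
        p_adj = pmin(1, m * p), degenerate = degenerate,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch pairwise comparisons of cell means
#'
#' Computes the marginal mean of every design cell (averaging each
#' subject's replicate observations first, so the subject is the
#' observational unit), then Welch's t-test with Satterthwaite degrees of
#' freedom for every pair of cells, Bonferroni-corrected over the
#' `k*(k-1)/2` pair family.
#'
#' @param data long data.frame
#' @param dv,subject column names
#' @param cells character vector of factor columns defining the cell grid
#' @return data.frame: `cell1`, `cell2`, `mean1`, `mean2`, `t`, `df`, `p`,
#'   `p_adj`, `degenerate`
#' @export
welch_pairwise <- function(data, dv, subject, cells) {
  key <- interaction(data[, cells, drop = FALSE], drop = TRUE, sep = ".")
  agg <- stats::aggregate(data[[dv]],
                          by = list(cell = key, subject = data[[subject]]),
                          FUN = mean)
  split_vals <- split(agg$x, agg$cell)
  split_vals <- split_vals[vapply(split_vals, length, integer(1)) >= 2]
  nm <- names(split_vals)
  rows <- list()
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j <= i) next
      x <- split_vals[[i]]
      y <- split_vals[[j]]
      degenerate <- stats::sd(x) == 0 && stats::sd(y) == 0
      if (degenerate) {
        tv <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
        df <- NA_real_
        p <- if (tv == 0) 1 else 0
      } else {
        tt <- stats::t.test(x, y, var.equal = FALSE)
        tv <- unname(tt$statistic)
        df <- unname(tt$parameter)
        p <- tt$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        cell1 = nm[i], cell2 = nm[j], mean1 = mean(x), mean2 = mean(y),
        t = tv, df = df, p = p, p_adj = NA_real_, degenerate = degenerate,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, nrow(out) * out$p)
  rownames(out) <- NULL
  out
}

#' Forced-entry multiple regression
#'
#' Ordinary least squares with all predictors entered simultaneously.
#' Reports unstandardized coefficients (B), standardized coefficients
#' (beta, computed from the sample SDs of the included complete cases),
#' per-predictor t and p, and the model F test with adjusted R-squared.
#'
#' @param data data.frame
#' @param response response column name
#' @param predictors character vector of predictor column names (numeric,
#'   logical, or two-level factors)
#' @return list of class `regression_result`: `coefficients` data.frame
#'   (`term`, `B`, `beta`, `t`, `p`), `F`, `df`, `p`, `r_squared`,
#'   `adj_r_squared`, `n`
#' @export
forced_entry_regression <- function(data, response, predictors) {
  d <- data[stats::complete.cases(data[, c(response, predictors)]),
            c(response, predictors)]
  n <- nrow(d)
  if (n <= length(predictors) + 1)
    stop("forced_entry_regression: need n > p + 1 complete cases", call. = FALSE)
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("forced_entry_regression: rank-deficient fit; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  mm <- stats::model.matrix(fit)
  sdx <- apply(mm, 2, stats::sd)
  sdy <- stats::sd(d[[response]])
  beta <- ct[, "Estimate"] * sdx[rownames(ct)] / sdy
  beta["(Intercept)"] <- NA_real_
  coef_tab <- data.frame(term = rownames(ct), B = ct[, "Estimate"],
                         beta = unname(beta), t = ct[, "t value"],
                         p = ct[, "Pr(>|t|)"], stringsAsFactors = FALSE)
  rownames(coef_tab) <- NULL
  fstat <- sm$fstatistic
  structure(list(
    coefficients = coef_tab,
    F = unname(fstat[1]), df = unname(fstat[2:3]),
    p = if (is.null(fstat)) NA_real_ else
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared, n = n
  ), class = "regression_result")
}
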