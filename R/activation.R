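#' Build the GLM design matrix for a block paradigm
#'
#' Columns: an intercept, the MA-task boxcar convolved with the HRF, and the
#' rest boxcar convolved with the HRF. Prompts are left unmodeled.
#'
#' @param paradigm A `paradigm_spec`.
#' @param hrf An `hrf_kernel` (default `canonical_hrf(paradigm$fs)`).
#' @param include_rest Model rest as an explicit regressor (default TRUE).
#' @param match_preprocess Apply the same detrending and zero-phase
#'   low-pass to the task regressors that the data received (default TRUE).
#'   Detrending and filtering are linear operations, so filtering the
#'   design identically keeps the amplitude estimates unbiased; an
#'   unfiltered design against filtered data attenuates them.
#' @param detrend_order,cutoff,filter_order Preprocessing settings to
#'   mirror (defaults match [run_preprocess()]).
#' @return Object of class `design_matrix`: list with `X` (n x p matrix with
#'   column names `intercept`, `MA`, `rest`), `n`, `p`.
#' @export
build_design <- function(paradigm, hrf = NULL, include_rest = TRUE,
                         match_preprocess = TRUE, detrend_order = 1,
                         cutoff = 0.1, filter_order = 3) {
  if (is.null(hrf)) hrf <- canonical_hrf(paradigm$fs)
  regress <- function(box) {
    r <- hrf_convolve(box, hrf)
    if (match_preprocess) {
      r <- detrend_poly(r, detrend_order)
      r <- lowpass_filter(r, cutoff, filter_order, paradigm$fs)
    }
    r
  }
  X <- cbind(intercept = 1, MA = regress(paradigm_boxcar(paradigm, "MA")))
  if (include_rest && any(paradigm$events$label == "rest")) {
    X <- cbind(X, rest = regress(paradigm_boxcar(paradigm, "rest")))
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("Degenerate design: need more timepoints than regressors (n > p).", call. = FALSE)
  structure(list(X = X, n = n, p = p), class = "design_matrix")
}

#' Fit the channel-wise general linear model
#'
#' Ordinary least squares of each channel's time course on the design
#' matrix: `y = X beta + e`, solved per channel via the QR decomposition.
#'
#' @param y Channels x time matrix (or a `hemo_recording`, in which case
#'   `species` selects the signal).
#' @param design A `design_matrix`.
#' @param species For `hemo_recording` input: `"hbo"`, `"hbr"` or `"hbt"`.
#' @return Object of class `nirs_glm`: `beta` (channels x regressors),
#'   `se` (matching standard errors), `sigma2`, `dof`, `residuals`,
#'   `fitted`, `design`.
#' @export
fit_glm <- function(y, design, species = c("hbo", "hbr", "hbt")) {
  if (inherits(y, "hemo_recording")) {
    species <- match.arg(species)
    y <- y[[species]]
  }
  y <- rbind(y)
  X <- design$X
  if (ncol(y) != nrow(X)) stop("Signal length does not match the design matrix.", call. = FALSE)
  if (!all(is.finite(y))) stop("Signal must be finite.", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop(sprintf("Design matrix is rank deficient (collinear: %s).",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  bt <- qr.coef(qrX, t(y)) # p x channels
  fitted <- t(X %*% bt)
  resid <- y - fitted
  dof <- nrow(X) - ncol(X)
  sigma2 <- rowSums(resid^2) / dof
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(outer(sigma2, diag(xtx_inv)))
  colnames(se) <- colnames(X)
  structure(
    list(
      beta = t(bt), se = se, sigma2 = sigma2, dof = dof,
      residuals = resid, fitted = fitted, design = design
    ),
    class = "nirs_glm"
  )
}

#' @export
tidy.nirs_glm <- function(x, conf.level = 0.95, ...) {
  tcrit <- stats::qt(1 - (1 - conf.level) / 2, x$dof)
  out <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(x$beta), channel = dplyr::row_number()),
    -"channel", names_to = "term", values_to = "estimate"
  )
  se_long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(x$se), channel = dplyr::row_number()),
    -"channel", names_to = "term", values_to = "std.error"
  )
  out <- dplyr::left_join(out, se_long, by = c("channel", "term"))
  dplyr::mutate(out,
    statistic = .data$estimate / .data$std.error,
    conf.low = .data$estimate - tcrit * .data$std.error,
    conf.high = .data$estimate + tcrit * .data$std.error
  )
}

#' @export
glance.nirs_glm <- function(x, ...) {
  tibble::tibble(
    n_channels = nrow(x$beta), n_timepoints = x$design$n,
    p = x$design$p, dof = x$dof, mean_sigma2 = mean(x$sigma2)
  )
}

#' Normality and variance-homogeneity checks on activation amplitudes
#'
#' Shapiro-Wilk normality test per channel (per group when `group` is
#' given) and, across groups, Levene's test of variance homogeneity
#' (center = mean, matching the classical formulation).
#'
#' @param beta Subjects x channels matrix of GLM amplitudes.
#' @param group Optional factor of group labels (length = subjects).
#' @return List with tibbles `shapiro` (`channel`, `group`, `W`, `p.value`)
#'   and `levene` (`channel`, `statistic`, `p.value`; NULL without groups).
#' @export
assumption_checks <- function(beta, group = NULL) {
  beta <- rbind(beta)
  n_ch <- ncol(beta)
  grp <- if (is.null(group)) factor(rep("all", nrow(beta))) else factor(group)
  sw <- purrr::map_dfr(seq_len(n_ch), function(ch) {
    purrr::map_dfr(levels(grp), function(g) {
      x <- beta[grp == g, ch]
      if (length(x) < 3) stop("Shapiro-Wilk needs at least 3 samples per group.", call. = FALSE)
      if (stats::sd(x) < .Machine$double.eps) {
        warning("Constant amplitudes in a group; normality test degenerate.", call. = FALSE)
        return(tibble::tibble(channel = ch, group = g, W = NA_real_, p.value = NA_real_))
      }
      s <- stats::shapiro.test(x)
      tibble::tibble(channel = ch, group = g, W = unname(s$statistic), p.value = s$p.value)
    })
  })
  lev <- NULL
  if (!is.null(group) && nlevels(grp) > 1) {
    lev <- purrr::map_dfr(seq_len(n_ch), function(ch) {
      lt <- car::leveneTest(beta[, ch], grp, center = mean)
      tibble::tibble(
        channel = ch, statistic = lt[1, "F value"], p.value = lt[1, "Pr(>F)"]
      )
    })
  }
  list(shapiro = sw, levene = lev)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjusted p-values (monotone, clipped at 1), applied within
#' one test family (one hemoglobin species x gender x test).
#'
#' @param p Vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values of the same length.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

new_stat_map <- function(t, p, test, alpha = 0.05) {
  p_adj <- fdr_adjust(p)
  structure(
    tibble::tibble(
      channel = seq_along(t), t = t, p.value = p,
      p.adjusted = p_adj, significant = p_adj < alpha
    ),
    test = test, alpha = alpha,
    class = c("stat_map", "tbl_df", "tbl", "data.frame")
  )
}

#' Paired t map: task versus rest amplitudes
#'
#' Per-channel paired t test of the MA-task amplitudes against the rest
#' amplitudes over subjects, two-sided, with BH-FDR adjustment across
#' channels.
#'
#' @param beta_task,beta_rest Subjects x channels matrices with matched
#'   rows.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return A `stat_map` tibble: `channel`, `t`, `p.value`, `p.adjusted`,
#'   `significant`.
#' @export
paired_t_map <- function(beta_task, beta_rest, alpha = 0.05) {
  beta_task <- rbind(beta_task)
  beta_rest <- rbind(beta_rest)
  if (!identical(dim(beta_task), dim(beta_rest))) {
    stop("Task and rest amplitude matrices must match.", call. = FALSE)
  }
  if (nrow(beta_task) < 2) stop("Paired t test needs at least 2 subjects.", call. = FALSE)
  res <- purrr::map(seq_len(ncol(beta_task)), function(ch) {
    d <- beta_task[, ch] - beta_rest[, ch]
    if (stats::sd(d) < .Machine$double.eps) {
      stop(sprintf("Channel %d: zero variance of paired differences; t undefined.", ch),
        call. = FALSE
      )
    }
    tt <- stats::t.test(beta_task[, ch], beta_rest[, ch], paired = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  new_stat_map(
    vapply(res, `[[`, 0, "t"), vapply(res, `[[`, 0, "p"),
    test = "paired MA vs rest", alpha = alpha
  )
}

#' Two-sample t map: group contrast of task amplitudes
#'
#' Per-channel two-sample t test (pooled variance by default, Welch
#' optional) between two groups of subjects, two-sided, BH-FDR adjusted
#' across channels.
#'
#' @param beta_a,beta_b Subjects x channels amplitude matrices for the two
#'   groups.
#' @param var.equal Pooled variance (default TRUE).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return A `stat_map` tibble.
#' @export
group_t_map <- function(beta_a, beta_b, var.equal = TRUE, alpha = 0.05) {
  beta_a <- rbind(beta_a)
  beta_b <- rbind(beta_b)
  if (ncol(beta_a) != ncol(beta_b)) stop("Channel counts differ between groups.", call. = FALSE)
  if (nrow(beta_a) < 2 || nrow(beta_b) < 2) {
    stop("Two-sample t test needs at least 2 subjects per group.", call. = FALSE)
  }
  res <- purrr::map(seq_len(ncol(beta_a)), function(ch) {
    xa <- beta_a[, ch]
    xb <- beta_b[, ch]
    if (stats::sd(c(xa - mean(xa), xb - mean(xb))) < .Machine$double.eps) {
      stop(sprintf("Channel %d: zero within-group variance; t undefined.", ch), call. = FALSE)
    }
    tt <- stats::t.test(xa, xb, var.equal = var.equal)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  new_stat_map(
    vapply(res, `[[`, 0, "t"), vapply(res, `[[`, 0, "p"),
    test = "two-sample group contrast", alpha = alpha
  )
}

#' Pearson correlation between activation and a clinical marker
#'
#' @param beta Per-subject activation amplitudes (one channel).
#' @param marker Per-subject marker values, paired with `beta`.
#' @return Tibble with `r`, `p.value`, `n`.
#' @export
marker_correlation <- function(beta, marker) {
  ok <- is.finite(beta) & is.finite(marker)
  beta <- beta[ok]
  marker <- marker[ok]
  if (length(beta) < 3) stop("Correlation needs at least 3 paired values.", call. = FALSE)
  if (stats::sd(beta) < .Machine$double.eps || stats::sd(marker) < .Machine$double.eps) {
    stop("Correlation undefined: zero variance.", call. = FALSE)
  }
  ct <- stats::cor.test(beta, marker, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p.value = ct$p.value, n = length(beta))
}

#' Required sample size for a two-sample t test
#'
#' A priori power analysis for a two-sided independent-samples t test.
#' `method = "normal_approx"` applies the closed-form normal approximation
#' `n = 2 (z_{alpha/2} + z_beta)^2 / d^2` and rounds up. `method =
#' "noncentral_t"` solves the exact noncentral-t power equation by
#' iterating over integer group sizes and returns the smallest n whose
#' power reaches the target — the calculation a power-analysis program
#' performs. With alpha = 0.05, power = 0.80 and d = 0.5 the exact method
#' gives 64 per group; the normal approximation gives 63.
#'
#' @param power Target power 1 - beta (default 0.80).
#' @param alpha Two-sided significance level (default 0.05).
#' @param d Standardized effect size (Cohen's d), > 0.
#' @param method `"noncentral_t"` (default) or `"normal_approx"`.
#' @return Tibble with `n_per_group`, `n_total`, `achieved_power`,
#'   `method`.
#' @export
required_sample_size <- function(power = 0.80, alpha = 0.05, d = 0.5,
                                 method = c("noncentral_t", "normal_approx")) {
  method <- match.arg(method)
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1)) {
    stop("`alpha` and `power` must lie in (0, 1).", call. = FALSE)
  }
  if (d <= 0) stop("Effect size `d` must be positive (n is infinite at d = 0).", call. = FALSE)
  if (method == "normal_approx") {
    n <- ceiling(2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / d^2)
    ach <- two_sample_t_power(n, d, alpha)
  } else {
    n <- 2
    while (two_sample_t_power(n, d, alpha) < power && n < 1e7) n <- n + 1
    ach <- two_sample_t_power(n, d, alpha)
  }
  tibble::tibble(
    n_per_group = as.integer(n), n_total = 2L * as.integer(n),
    achieved_power = ach, method = method
  )
}

# Exact power of the two-sided two-sample t test at group size n,
# effect size d, via the noncentral t distribution.
two_sample_t_power <- function(n, d, alpha) {
  df <- 2 * n - 2
  if (df < 1) return(0)
  ncp <- d * sqrt(n / 2)
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp, lower.tail = FALSE) + stats::pt(-crit, df, ncp)
}

#' Per-subject GLM amplitudes for a preprocessed cohort
#'
#' Fits the channel-wise GLM to every kept subject and collects the MA and
#' rest amplitudes.
#'
#' @param hemo_list Named list of `hemo_recording` (from
#'   [preprocess_cohort()]).
#' @param paradigm The `paradigm_spec`.
#' @param species `"hbo"`, `"hbr"` or `"hbt"`.
#' @param hrf Optional `hrf_kernel`.
#' @return List with matrices `beta_ma` and `beta_rest`
#'   (subjects x channels, rownames = subject ids) and `glms` (list).
#' @export
cohort_glm <- function(hemo_list, paradigm, species = "hbo", hrf = NULL) {
  design <- build_design(paradigm, hrf)
  glms <- lapply(hemo_list, fit_glm, design = design, species = species)
  beta_ma <- do.call(rbind, lapply(glms, function(g) g$beta[, "MA"]))
  beta_rest <- do.call(rbind, lapply(glms, function(g) g$beta[, "rest"]))
  rownames(beta_ma) <- rownames(beta_rest) <- names(hemo_list)
  list(beta_ma = beta_ma, beta_rest = beta_rest, glms = glms, design = design)
}
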