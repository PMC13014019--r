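#' Segment a preprocessed recording into 60-s trials
#'
#' One segment per trial: the 30-s MA block concatenated with its 30-s rest
#' block (prompts excluded), per hemoglobin species.
#'
#' @param hemo A `hemo_recording`.
#' @param paradigm The matching `paradigm_spec`.
#' @param species `"hbo"`, `"hbr"` or `"hbt"`.
#' @param label Optional class label attached to every segment.
#' @param gender Optional gender tag.
#' @return List of `trial_segment` objects: each a list with `data`
#'   (channels x time matrix), `subject_id`, `trial`, `species`, `label`,
#'   `gender`.
#' @export
segment_trials <- function(hemo, paradigm, species = c("hbo", "hbr", "hbt"),
                           label = NA, gender = NA_character_) {
  species <- match.arg(species)
  sig <- hemo[[species]]
  if (ncol(sig) != paradigm$n_samples) {
    stop("Recording length does not match the paradigm.", call. = FALSE)
  }
  fs <- paradigm$fs
  tt <- paradigm_times(paradigm)
  ev <- paradigm$events
  purrr::map(seq_len(paradigm$n_trials), function(i) {
    ma <- ev[ev$label == "MA" & ev$trial == i, ]
    rest <- ev[ev$label == "rest" & ev$trial == i, ]
    pick <- function(e) {
      which(tt >= e$onset_s - 1e-9 & tt < e$onset_s + e$duration_s - 1e-9)
    }
    idx <- c(pick(ma), pick(rest))
    structure(
      list(
        data = sig[, idx, drop = FALSE], subject_id = hemo$subject_id,
        trial = i, species = species, label = label, gender = gender
      ),
      class = "trial_segment"
    )
  })
}

#' Select the dominant negatively correlated channel pair
#'
#' For each training segment, computes the pairwise Pearson correlation
#' matrix across channels and records the pair with the most negative
#' correlation; returns the pair selected most frequently across segments.
#' Ties are broken by the more negative mean correlation at selection, then
#' lexicographically. Constant channels are excluded from candidacy with a
#' warning. The pair must be estimated on training data only.
#'
#' @param segments List of `trial_segment` (training split).
#' @return Object of class `channel_pair`: list with `pair` (i < j),
#'   `frequency` (selection count), `n_segments`, `mean_correlation`,
#'   `tally` (tibble of all selected pairs).
#' @export
select_negative_pair <- function(segments) {
  if (length(segments) < 1) stop("Need at least one training segment.", call. = FALSE)
  picks <- purrr::map_dfr(segments, function(seg) {
    x <- t(seg$data) # time x channels
    sds <- apply(x, 2, stats::sd)
    keep <- sds > .Machine$double.eps
    if (!all(keep)) {
      warning(sprintf(
        "Constant channel(s) %s excluded from pair selection.",
        paste(which(!keep), collapse = ", ")
      ), call. = FALSE)
    }
    cm <- suppressWarnings(stats::cor(x))
    cm[!keep, ] <- NA
    cm[, !keep] <- NA
    cm[lower.tri(cm, diag = TRUE)] <- NA
    if (all(is.na(cm))) return(NULL)
    ij <- arrayInd(which.min(cm), dim(cm))
    tibble::tibble(i = ij[1], j = ij[2], corr = cm[ij])
  })
  if (nrow(picks) == 0) stop("No valid channel pairs in training segments.", call. = FALSE)
  tally <- picks |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(
      n = dplyr::n(), mean_corr = mean(.data$corr), .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$mean_corr, .data$i, .data$j)
  structure(
    list(
      pair = c(tally$i[1], tally$j[1]), frequency = tally$n[1],
      n_segments = length(segments), mean_correlation = tally$mean_corr[1],
      tally = tally
    ),
    class = "channel_pair"
  )
}

#' @export
print.channel_pair <- function(x, ...) {
  cat(sprintf(
    "<channel_pair> (%d, %d): selected in %d/%d segments, mean r = %.3f\n",
    x$pair[1], x$pair[2], x$frequency, x$n_segments, x$mean_correlation
  ))
  invisible(x)
}

#' Time-domain summary statistics of a signal
#'
#' Sample mean, sample variance (denominator n-1), moment skewness
#' g1 = m3 / m2^(3/2) and Fisher excess kurtosis g2 = m4 / m2^2 - 3.
#' Constant signals report zero skewness/kurtosis with `degenerate = TRUE`.
#'
#' @param x Numeric vector, length >= 4.
#' @return Tibble with `mean`, `variance`, `skewness`, `kurtosis`,
#'   `degenerate`.
#' @export
timedomain_stats <- function(x) {
  if (length(x) < 4) stop("Need at least 4 samples.", call. = FALSE)
  v <- stats::var(x)
  if (v < .Machine$double.eps) {
    return(tibble::tibble(
      mean = mean(x), variance = 0, skewness = 0, kurtosis = 0, degenerate = TRUE
    ))
  }
  tibble::tibble(
    mean = mean(x), variance = v,
    skewness = e1071::skewness(x, type = 1),
    kurtosis = e1071::kurtosis(x, type = 1),
    degenerate = FALSE
  )
}

#' Per-channel PCA over trials
#'
#' Treats trials as observations and that channel's time samples as
#' variables; mean-centers and keeps the top `k` principal components.
#' The fitted basis is reused to project held-out trials without refitting.
#'
#' @param segments Training `trial_segment` list.
#' @param channel Channel index.
#' @param k Number of components (default 3).
#' @return Object of class `channel_pca`: `center`, `rotation`
#'   (time x k), `scores` (train trials x k), `sdev`, `channel`, `k`.
#' @export
channel_pca <- function(segments, channel, k = 3) {
  X <- do.call(rbind, purrr::map(segments, ~ .x$data[channel, ]))
  if (nrow(X) < k) stop("Need at least k training trials for k components.", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev > 1e-12) < k) {
    stop("Requested more components than the data's rank.", call. = FALSE)
  }
  structure(
    list(
      center = pc$center, rotation = pc$rotation[, seq_len(k), drop = FALSE],
      scores = pc$x[, seq_len(k), drop = FALSE], sdev = pc$sdev,
      channel = channel, k = k
    ),
    class = "channel_pca"
  )
}

# Project (possibly held-out) trials of one channel onto a fitted basis.
pca_project <- function(fit, segments) {
  X <- do.call(rbind, purrr::map(segments, ~ .x$data[fit$channel, ]))
  sweep(X, 2, fit$center) %*% fit$rotation
}

#' Fit the feature-extraction state on training segments
#'
#' Estimates everything the five feature families need, on the training
#' split only: the dominant negatively correlated channel pair (A, C),
#' per-channel PCA bases over trials (B, C), per-(channel, IMF-index) PCA
#' bases of EMD components (D), and the per-trial GLM design (E).
#'
#' @param train_segments Training `trial_segment` list.
#' @param sets Character subset of `c("A","B","C","D","E")` to prepare
#'   (default all).
#' @param n_pc Components per channel for set B/C (default 3).
#' @param n_imf IMF indices kept for set D (default 3, zero-padded).
#' @param hrf `hrf_kernel` for the per-trial GLM of set E.
#' @param fs Sampling rate (default 1).
#' @param block_s MA/rest block length within a segment (default 30).
#' @return Object of class `feature_state`.
#' @export
fit_feature_state <- function(train_segments, sets = c("A", "B", "C", "D", "E"),
                              n_pc = 3, n_imf = 3, hrf = NULL, fs = 1,
                              block_s = 30) {
  stopifnot(length(train_segments) >= 1)
  n_ch <- nrow(train_segments[[1]]$data)
  state <- list(
    sets = sets, n_pc = n_pc, n_imf = n_imf, n_channels = n_ch,
    fs = fs, block_s = block_s
  )
  if (any(c("A", "C") %in% sets)) {
    state$pair <- select_negative_pair(train_segments)
  }
  if (any(c("B", "C") %in% sets)) {
    state$pca <- lapply(seq_len(n_ch), function(ch) channel_pca(train_segments, ch, n_pc))
  }
  if ("D" %in% sets) {
    imf_rows <- lapply(seq_len(n_ch), function(ch) {
      lapply(train_segments, function(seg) segment_imfs(seg$data[ch, ], n_imf))
    })
    state$emd_pca <- lapply(seq_len(n_ch), function(ch) {
      lapply(seq_len(n_imf), function(k) {
        X <- do.call(rbind, lapply(imf_rows[[ch]], function(m) m[k, ]))
        pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
        list(center = pc$center, rotation = pc$rotation[, 1, drop = FALSE])
      })
    })
  }
  if ("E" %in% sets) {
    state$trial_design <- trial_design(
      n_time = ncol(train_segments[[1]]$data),
      block_s = block_s, fs = fs, hrf = hrf
    )
  }
  structure(state, class = "feature_state")
}

# EMD of one trial channel, first n_imf IMFs aligned by index and
# zero-padded when the decomposition yields fewer.
segment_imfs <- function(x, n_imf) {
  dec <- emd_decompose(x)
  out <- matrix(0, n_imf, length(x))
  k <- min(n_imf, dec$n_imfs)
  if (k > 0) out[seq_len(k), ] <- dec$imfs[seq_len(k), , drop = FALSE]
  out
}

# Design matrix for one 60-s trial window: intercept + HRF-convolved MA
# boxcar (first block) + HRF-convolved rest boxcar (second block).
trial_design <- function(n_time, block_s = 30, fs = 1, hrf = NULL) {
  if (is.null(hrf)) hrf <- canonical_hrf(fs)
  n_block <- round(block_s * fs)
  ma_box <- c(rep(1, n_block), rep(0, n_time - n_block))
  rest_box <- c(rep(0, n_block), rep(1, n_time - n_block))
  X <- cbind(
    intercept = 1,
    MA = hrf_convolve(ma_box, hrf),
    rest = hrf_convolve(rest_box, hrf)
  )
  structure(list(X = X, n = n_time, p = ncol(X)), class = "design_matrix")
}

#' Per-trial GLM activation amplitudes (feature set E)
#'
#' Fits the trial-window GLM to one segment and returns the per-channel
#' MA amplitude.
#'
#' @param segment A `trial_segment`.
#' @param design The trial `design_matrix` from the fitted state.
#' @return Numeric vector of per-channel MA betas.
#' @export
trial_beta <- function(segment, design) {
  fit_glm(segment$data, design)$beta[, "MA"]
}

#' Extract one of the five feature families
#'
#' Builds the feature matrix for a segment list using a state fitted on
#' training data ([fit_feature_state()]); applying it to held-out segments
#' never refits anything.
#'
#' * **A** (8 columns): mean, variance, skewness, kurtosis of the two
#'   selected negatively correlated channels.
#' * **B** (3 x channels): first 3 PCA scores of every channel.
#' * **C** (14): A plus the 3 PCA scores of each of the two pair channels.
#' * **D** (3 x channels): first-PC score per IMF index per channel after
#'   EMD.
#' * **E** (channels): per-trial GLM MA amplitudes.
#'
#' @param segments List of `trial_segment`.
#' @param set_id One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @param state A `feature_state` fitted on the training split.
#' @return A tibble (rows = trials) with named feature columns plus
#'   `subject_id`, `trial`, `label`, `gender`; attribute `set_id`.
#' @export
extract_features <- function(segments, set_id, state) {
  if (!set_id %in% c("A", "B", "C", "D", "E")) {
    stop(sprintf("Unknown feature set '%s'.", set_id), call. = FALSE)
  }
  meta <- tibble::tibble(
    subject_id = purrr::map_chr(segments, "subject_id"),
    trial = purrr::map_int(segments, ~ as.integer(.x$trial)),
    label = unlist(purrr::map(segments, ~ .x$label %||% NA)),
    gender = purrr::map_chr(segments, ~ as.character(.x$gender %||% NA))
  )
  feats <- switch(set_id,
    A = features_a(segments, state),
    B = features_b(segments, state),
    C = cbind(features_a(segments, state), features_b(segments, state, state$pair$pair)),
    D = features_d(segments, state),
    E = features_e(segments, state)
  )
  out <- dplyr::bind_cols(meta, tibble::as_tibble(feats))
  if (anyNA(feats)) stop("Feature matrix contains NA.", call. = FALSE)
  attr(out, "set_id") <- set_id
  out
}

features_a <- function(segments, state) {
  pair <- state$pair$pair
  rows <- purrr::map(segments, function(seg) {
    unlist(lapply(pair, function(ch) {
      st <- timedomain_stats(seg$data[ch, ])
      c(mean = st$mean, var = st$variance, skew = st$skewness, kurt = st$kurtosis)
    }))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- as.vector(t(outer(
    paste0("ch", pair), c("mean", "var", "skew", "kurt"), paste, sep = "_"
  )))
  m
}

features_b <- function(segments, state, channels = NULL) {
  channels <- channels %||% seq_len(state$n_channels)
  blocks <- lapply(channels, function(ch) {
    sc <- pca_project(state$pca[[ch]], segments)
    colnames(sc) <- paste0("ch", ch, "_pc", seq_len(ncol(sc)))
    sc
  })
  do.call(cbind, blocks)
}

features_d <- function(segments, state) {
  blocks <- lapply(seq_len(state$n_channels), function(ch) {
    sc <- sapply(seq_len(state$n_imf), function(k) {
      fit <- state$emd_pca[[ch]][[k]]
      X <- do.call(rbind, lapply(segments, function(seg) {
        segment_imfs(seg$data[ch, ], state$n_imf)[k, ]
      }))
      as.numeric(sweep(X, 2, fit$center) %*% fit$rotation)
    })
    sc <- matrix(sc, nrow = length(segments))
    colnames(sc) <- paste0("ch", ch, "_imf", seq_len(state$n_imf), "_pc1")
    sc
  })
  do.call(cbind, blocks)
}

features_e <- function(segments, state) {
  m <- do.call(rbind, lapply(segments, trial_beta, design = state$trial_design))
  colnames(m) <- paste0("ch", seq_len(ncol(m)), "_beta")
  m
}
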