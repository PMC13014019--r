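#' Tidy a hemoglobin recording into long format
#'
#' @param x A `hemo_recording`.
#' @param ... Unused.
#' @return Long tibble: `subject_id`, `channel`, `t_s`, `dHbO`, `dHbR`,
#'   `dHbT` (umol/l).
#' @export
tidy.hemo_recording <- function(x, ...) {
  n_ch <- nrow(x$hbo)
  n_t <- ncol(x$hbo)
  tibble::tibble(
    subject_id = x$subject_id,
    channel = rep(seq_len(n_ch), each = n_t),
    t_s = rep(seq(0, by = 1 / x$fs, length.out = n_t), n_ch),
    dHbO = as.numeric(t(x$hbo)),
    dHbR = as.numeric(t(x$hbr)),
    dHbT = as.numeric(t(x$hbt))
  )
}

#' Write a simulated cohort to long-format CSV
#'
#' Emits `intensity.csv` (columns `subject_id`, `group`, `gender`,
#' `wavelength_nm`, `channel`, `t_s`, `intensity`) and `subjects.csv` (the
#' metadata table) into a directory.
#'
#' @param cohort A `nirs_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wl <- cohort$optodes$wavelengths_nm
  long <- purrr::map_dfr(cohort$recordings, function(rec) {
    d <- dim(rec$intensity)
    tt <- seq(0, by = 1 / cohort$paradigm$fs, length.out = d[3])
    purrr::map_dfr(1:2, function(w) {
      tibble::tibble(
        subject_id = rec$subject$subject_id,
        group = rec$subject$group,
        gender = rec$subject$gender,
        wavelength_nm = wl[w],
        channel = rep(seq_len(d[2]), each = d[3]),
        t_s = rep(tt, d[2]),
        intensity = as.numeric(t(rec$intensity[w, , ]))
      )
    })
  })
  f1 <- file.path(dir, "intensity.csv")
  f2 <- file.path(dir, "subjects.csv")
  readr::write_csv(long, f1)
  readr::write_csv(cohort$subjects, f2)
  invisible(c(f1, f2))
}

#' Read a cohort from long-format CSV
#'
#' Inverse of [write_cohort_csv()]; the optode configuration and paradigm
#' are supplied by the caller (they are acquisition constants, not data).
#'
#' @param dir Directory containing `intensity.csv` and `subjects.csv`.
#' @param paradigm The `paradigm_spec` used at acquisition.
#' @param optodes The `optode_config` used at acquisition.
#' @return A `nirs_cohort` (without simulation ground truth).
#' @export
read_cohort_csv <- function(dir, paradigm = build_paradigm(),
                            optodes = optode_config()) {
  long <- readr::read_csv(file.path(dir, "intensity.csv"),
    show_col_types = FALSE
  )
  subjects <- readr::read_csv(file.path(dir, "subjects.csv"),
    show_col_types = FALSE
  )
  wl <- sort(unique(long$wavelength_nm))
  recs <- lapply(unique(long$subject_id), function(sid) {
    sub <- long[long$subject_id == sid, ]
    n_ch <- max(sub$channel)
    n_t <- length(unique(sub$t_s))
    I <- array(NA_real_, c(2, n_ch, n_t))
    for (w in 1:2) {
      sw <- sub[sub$wavelength_nm == wl[w], ]
      sw <- sw[order(sw$channel, sw$t_s), ]
      I[w, , ] <- matrix(sw$intensity, n_ch, n_t, byrow = TRUE)
    }
    meta <- subjects[subjects$subject_id == sid, ]
    structure(
      list(
        intensity = I, optodes = optodes, paradigm = paradigm,
        subject = subject_record(
          sid,
          group = meta$group, gender = meta$gender,
          age = meta$age, education = meta$education,
          true_beta = numeric(n_ch)
        ),
        fs = paradigm$fs, subject_id = sid
      ),
      class = "raw_intensity_recording"
    )
  })
  structure(
    list(
      recordings = recs, subjects = subjects, paradigm = paradigm,
      optodes = optodes, noise = NULL, seed = NA
    ),
    class = "nirs_cohort"
  )
}

#' Export a stat map as a results-table TSV
#'
#' @param map A `stat_map`.
#' @param path Output TSV path.
#' @param species Hemoglobin species label for the table.
#' @return Invisibly, `path`.
#' @export
write_stat_map_tsv <- function(map, path, species = "HbO") {
  out <- dplyr::mutate(tibble::as_tibble(map),
    hemoglobin = species, .before = 1
  )
  readr::write_tsv(out, path)
  invisible(path)
}
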