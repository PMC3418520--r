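#' Write / read a simulated session
#'
#' A session directory holds `summary.csv` (one row per trial),
#' `records.csv` (long format: trial index, sample index, t, vy, fx, x for
#' every stored series; units s, m/s, N, m) and `manifest.json` (learner name,
#' parameters, seed, profile settings). All files are plain text.
#'
#' @param session A [run_subject()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly (write); a `reach_session` (read). Round-tripped
#'   sessions support the full analysis surface
#'   ([analyze_constant_phase()], [cohort_contrast()], ...).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(session$summary),
                   file.path(dir, "summary.csv"), row.names = FALSE, na = "")
  recs <- session$records
  if (length(recs) > 0L) {
    long <- do.call(rbind, lapply(names(recs), function(nm) {
      r <- recs[[nm]]
      k <- length(r$vy)
      data.frame(trial = as.integer(nm), sample = seq_len(k) - 1L,
                 t = (seq_len(k) - 1L) * r$dt, vy = r$vy, fx = r$fx, x = r$x)
    }))
    utils::write.csv(long, file.path(dir, "records.csv"), row.names = FALSE)
  }
  manifest <- list(
    learner_name = session$learner_name,
    params = session$params,
    seed = session$seed,
    profile = list(distance = session$profile$distance,
                   duration = session$profile$duration,
                   dt = session$profile$dt),
    index_base = 0L
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  summary <- utils::read.csv(file.path(dir, "summary.csv"),
                             stringsAsFactors = FALSE)
  summary$sequence_id <- as.integer(summary$sequence_id)
  summary$block_id <- as.integer(summary$block_id)
  summary <- tibble::as_tibble(summary)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  profile <- minjerk_profile(manifest$profile$distance,
                             manifest$profile$duration, manifest$profile$dt)
  records <- list()
  rec_path <- file.path(dir, "records.csv")
  if (file.exists(rec_path)) {
    long <- utils::read.csv(rec_path)
    for (tr in unique(long$trial)) {
      sub <- long[long$trial == tr, ]
      sub <- sub[order(sub$sample), ]
      i <- which(summary$index == tr)
      records[[as.character(tr)]] <- .trial_record(
        summary$trial_type[i], summary$B[i], summary$B_hat_used[i],
        list(dt = manifest$profile$dt, vy = sub$vy), sub$fx, sub$x)
    }
  }
  structure(list(summary = summary, records = records, profile = profile,
                 learner_name = manifest$learner_name,
                 params = manifest$params, seed = manifest$seed),
            class = "reach_session")
}
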