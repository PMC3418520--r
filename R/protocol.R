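#' Default protocol configuration
#'
#' Parameters of the three-phase force-field experiment: a null-field baseline,
#' a random-perturbations phase with short increasing sequences of viscous
#' fields embedded in a uniform random background, and a constant-perturbations
#' phase of fixed-amplitude blocks. Defaults reproduce the 780-trial protocol
#' (100 baseline + 200 random + 12 x 40 constant).
#'
#' @param n_baseline Number of baseline (null-field) trials.
#' @param n_random Number of random-perturbations trials.
#' @param n_constant Number of constant-perturbations trials; must be a
#'   multiple of `block_size`.
#' @param block_size Trials per constant-phase block.
#' @param constant_amplitudes Field amplitudes (Ns/m) of the constant
#'   conditions; each appears in exactly two blocks.
#' @param random_amplitudes Amplitude set (Ns/m) for the uniform random
#'   background of the random phase.
#' @param sequence_amplitudes Amplitudes (Ns/m), in order, of each embedded
#'   increasing sequence.
#' @param n_sequences Number of embedded sequences (each followed by one
#'   error-clamp trial).
#' @param clamp_fraction_random Fraction of random-phase trials that are
#'   error clamps (sequence-trailing clamps count toward this total).
#' @param clamps_per_block Error clamps per constant-phase block, never at the
#'   first trial of a block.
#' @param block_order Optional explicit ordering of constant-phase block
#'   amplitudes (length `n_constant / block_size`); `NULL` draws a
#'   seed-determined permutation, fixed across subjects.
#' @return A list of class `protocol_config`.
#' @seealso [build_schedule()]
#' @export
default_protocol_config <- function(n_baseline = 100L,
                                    n_random = 200L,
                                    n_constant = 480L,
                                    block_size = 40L,
                                    constant_amplitudes = c(1, 2, 2.5, 3, 4, 5),
                                    random_amplitudes = seq(1, 4, by = 0.5),
                                    sequence_amplitudes = c(1, 2, 3, 4),
                                    n_sequences = 10L,
                                    clamp_fraction_random = 0.10,
                                    clamps_per_block = 5L,
                                    block_order = NULL) {
  cfg <- list(
    n_baseline = as.integer(n_baseline),
    n_random = as.integer(n_random),
    n_constant = as.integer(n_constant),
    block_size = as.integer(block_size),
    constant_amplitudes = as.numeric(constant_amplitudes),
    random_amplitudes = as.numeric(random_amplitudes),
    sequence_amplitudes = as.numeric(sequence_amplitudes),
    n_sequences = as.integer(n_sequences),
    clamp_fraction_random = as.numeric(clamp_fraction_random),
    clamps_per_block = as.integer(clamps_per_block),
    block_order = if (is.null(block_order)) NULL else as.numeric(block_order)
  )
  class(cfg) <- "protocol_config"
  cfg
}

.check_config <- function(cfg) {
  if (cfg$n_baseline < 0L || cfg$n_random <= 0L || cfg$n_constant <= 0L) {
    stop("phase lengths must be positive", call. = FALSE)
  }
  if (cfg$clamp_fraction_random < 0 || cfg$clamp_fraction_random >= 1) {
    stop("clamp_fraction_random must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$n_constant %% cfg$block_size != 0L) {
    stop("n_constant must be a multiple of block_size", call. = FALSE)
  }
  n_blocks <- cfg$n_constant %/% cfg$block_size
  if (is.null(cfg$block_order)) {
    if (n_blocks != 2L * length(cfg$constant_amplitudes)) {
      stop("constant phase must hold each condition amplitude in exactly 2 blocks; ",
           "got ", n_blocks, " blocks for ", length(cfg$constant_amplitudes),
           " amplitudes", call. = FALSE)
    }
  } else {
    if (length(cfg$block_order) != n_blocks) {
      stop("block_order must have one amplitude per block (", n_blocks, ")",
           call. = FALSE)
    }
    want <- sort(rep(cfg$constant_amplitudes, times = 2L))
    if (!isTRUE(all.equal(sort(cfg$block_order), want))) {
      stop("block_order must be a permutation of each condition amplitude twice",
           call. = FALSE)
    }
  }
  if (cfg$clamps_per_block < 0L || cfg$clamps_per_block >= cfg$block_size) {
    stop("clamps_per_block must lie in [0, block_size)", call. = FALSE)
  }
  if (cfg$n_sequences * (length(cfg$sequence_amplitudes) + 1L) > cfg$n_random) {
    stop("sequences cannot fit in the random phase", call. = FALSE)
  }
  invisible(cfg)
}

# Place n non-overlapping blocks of `len` trials in `slots` positions with at
# least `gap` free trials between consecutive blocks. Uses the current RNG
# state; returns 1-based start indices in increasing order.
.place_blocks <- function(slots, n, len, gap = 1L) {
  if (n == 0L) return(integer(0))
  slack <- slots - n * len - (n - 1L) * gap
  if (slack < 0L) {
    stop("cannot place ", n, " non-overlapping blocks of length ", len,
         " (with gaps >= ", gap, ") in ", slots, " slots", call. = FALSE)
  }
  gaps <- as.vector(stats::rmultinom(1L, slack, rep(1, n + 1L)))
  starts <- integer(n)
  starts[1L] <- 1L + gaps[1L]
  if (n > 1L) {
    for (i in 2:n) starts[i] <- starts[i - 1L] + len + gap + gaps[i]
  }
  stopifnot(starts[n] + len - 1L <= slots)
  starts
}

#' Embed increasing sequences into a phase of trial slots
#'
#' Chooses non-overlapping placements for `n_sequences` blocks, each reserving
#' `length(amplitudes)` consecutive force trials plus one trailing error-clamp
#' trial, with at least one non-sequence trial between consecutive blocks.
#'
#' @param slots Number of available trial positions in the phase.
#' @param n_sequences Number of sequences to place.
#' @param amplitudes Field amplitudes (Ns/m) of one sequence, in order.
#' @param seed Integer seed; placements are deterministic given the seed.
#' @return Integer vector of 1-based start positions, one per sequence.
#' @examples
#' embed_sequences(200, 10, c(1, 2, 3, 4), seed = 1)
#' @export
embed_sequences <- function(slots, n_sequences, amplitudes, seed) {
  stopifnot(slots >= 0, n_sequences >= 0, length(amplitudes) >= 1)
  withr::with_seed(as.integer(seed),
    .place_blocks(as.integer(slots), as.integer(n_sequences),
                  length(amplitudes) + 1L, gap = 1L))
}

#' Build the three-phase experimental schedule
#'
#' Generates the full trial-by-trial protocol: `n_baseline` null-field trials;
#' a random phase whose background force amplitudes are drawn uniformly from
#' `random_amplitudes`, with `n_sequences` embedded increasing sequences each
#' trailed by an error-clamp trial and further clamps placed at random (total
#' clamp count = `round(clamp_fraction_random * n_random)`, free clamps never
#' adjacent to a sequence block); and a constant phase of equal-length blocks,
#' one amplitude per block, each amplitude in two blocks, with
#' `clamps_per_block` clamps randomly interspersed (never the first trial of a
#' block).
#'
#' @param config A [default_protocol_config()] list.
#' @param seed Integer seed; the schedule is deterministic given
#'   `(config, seed)`.
#' @return An object of class `reach_schedule`: a list with `trials` (a tibble
#'   with 0-based `index`, `phase`, `trial_type`, `B`, `sequence_id`,
#'   `block_id`), `config`, and `seed`.
#' @examples
#' sch <- build_schedule(seed = 1)
#' table(sch$trials$phase)
#' @export
build_schedule <- function(config = default_protocol_config(), seed = 1L) {
  .check_config(config)
  seed <- as.integer(seed)
  L <- length(config$sequence_amplitudes) + 1L

  trials <- withr::with_seed(seed, {
    # --- random phase layout -------------------------------------------------
    S <- config$n_random
    starts <- .place_blocks(S, config$n_sequences, L, gap = 1L)
    type <- rep("force_field", S)
    B <- rep(NA_real_, S)
    seq_id <- rep(NA_integer_, S)
    blocked <- logical(S)  # sequence blocks plus their adjacency margin
    for (i in seq_along(starts)) {
      s <- starts[i]
      idx <- s:(s + L - 2L)
      type[idx] <- "force_field"
      B[idx] <- config$sequence_amplitudes
      type[s + L - 1L] <- "error_clamp"
      seq_id[s:(s + L - 1L)] <- i
      blocked[max(1L, s - 1L):min(S, s + L)] <- TRUE
    }
    n_clamp_total <- round(config$clamp_fraction_random * S)
    n_free <- max(0L, as.integer(n_clamp_total) - config$n_sequences)
    if (n_free > 0L) {
      eligible <- which(!blocked)
      if (length(eligible) < n_free) {
        stop("cannot place ", n_free, " free clamp trials away from sequences",
             call. = FALSE)
      }
      free_pos <- sort(sample(eligible, n_free))
      type[free_pos] <- "error_clamp"
    }
    bg <- which(type == "force_field" & is.na(B))
    B[bg] <- sample(config$random_amplitudes, length(bg), replace = TRUE)

    random_df <- tibble::tibble(
      phase = "random", trial_type = type, B = B,
      sequence_id = seq_id, block_id = NA_integer_
    )

    # --- constant phase ------------------------------------------------------
    n_blocks <- config$n_constant %/% config$block_size
    order_B <- if (is.null(config$block_order)) {
      sample(rep(config$constant_amplitudes, times = 2L))
    } else {
      config$block_order
    }
    const_list <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      btype <- rep("force_field", config$block_size)
      if (config$clamps_per_block > 0L) {
        cpos <- sample(2:config$block_size, config$clamps_per_block)
        btype[cpos] <- "error_clamp"
      }
      const_list[[b]] <- tibble::tibble(
        phase = "constant", trial_type = btype,
        B = ifelse(btype == "force_field", order_B[b], NA_real_),
        sequence_id = NA_integer_, block_id = b
      )
    }

    baseline_df <- tibble::tibble(
      phase = "baseline", trial_type = "null_field", B = 0,
      sequence_id = NA_integer_, block_id = NA_integer_
    )[rep(1L, config$n_baseline), ]

    out <- rbind(baseline_df, random_df, do.call(rbind, const_list))
    out$index <- seq_len(nrow(out)) - 1L  # 0-based
    out[, c("index", "phase", "trial_type", "B", "sequence_id", "block_id")]
  })

  structure(list(trials = trials, config = config, seed = seed),
            class = "reach_schedule")
}

#' @export
print.reach_schedule <- function(x, ...) {
  tr <- x$trials
  cat("reach_schedule: ", nrow(tr), " trials (seed ", x$seed, ")\n", sep = "")
  cat("  phases:", paste(sprintf("%s=%d", names(table(tr$phase)),
                                 as.integer(table(tr$phase))), collapse = ", "), "\n")
  cat("  error clamps:", sum(tr$trial_type == "error_clamp"),
      "| sequences:", length(unique(stats::na.omit(tr$sequence_id))), "\n")
  invisible(x)
}

#' Validate a schedule against the protocol invariants
#'
#' Checks phase counts, baseline structure, random-phase amplitude set, clamp
#' counts, embedded-sequence structure, and constant-phase block structure.
#' Reports violations; never raises on schedule content.
#'
#' @param schedule A `reach_schedule` (or a list with `trials` and `config`).
#' @return Character vector of violation messages; empty if the schedule is
#'   valid.
#' @export
validate_schedule <- function(schedule) {
  tr <- schedule$trials
  cfg <- schedule$config
  bad <- character(0)
  note <- function(...) bad[[length(bad) + 1L]] <<- paste0(...)

  counts <- c(baseline = sum(tr$phase == "baseline"),
              random = sum(tr$phase == "random"),
              constant = sum(tr$phase == "constant"))
  if (!is.null(cfg)) {
    if (counts[["baseline"]] != cfg$n_baseline)
      note("baseline phase has ", counts[["baseline"]], " trials, expected ", cfg$n_baseline)
    if (counts[["random"]] != cfg$n_random)
      note("random phase has ", counts[["random"]], " trials, expected ", cfg$n_random)
    if (counts[["constant"]] != cfg$n_constant)
      note("constant phase has ", counts[["constant"]], " trials, expected ", cfg$n_constant)
  }

  base <- tr[tr$phase == "baseline", ]
  if (any(base$trial_type != "null_field" | base$B != 0))
    note("baseline must be null_field trials with B = 0")

  rnd <- tr[tr$phase == "random", ]
  bg <- rnd[rnd$trial_type == "force_field" & is.na(rnd$sequence_id), ]
  if (!is.null(cfg) && nrow(bg) > 0 && !all(bg$B %in% cfg$random_amplitudes))
    note("random-phase background amplitudes outside the configured set")
  if (!is.null(cfg)) {
    n_clamp <- sum(rnd$trial_type == "error_clamp")
    want <- max(round(cfg$clamp_fraction_random * cfg$n_random), cfg$n_sequences)
    if (n_clamp != want)
      note("random phase has ", n_clamp, " clamps, expected ", want)
  }

  for (sid in sort(unique(stats::na.omit(tr$sequence_id)))) {
    blk <- tr[!is.na(tr$sequence_id) & tr$sequence_id == sid, ]
    blk <- blk[order(blk$index), ]
    amps <- if (is.null(cfg)) c(1, 2, 3, 4) else cfg$sequence_amplitudes
    ok <- nrow(blk) == length(amps) + 1L &&
      all(diff(blk$index) == 1L) &&
      all(blk$trial_type[seq_along(amps)] == "force_field") &&
      isTRUE(all.equal(blk$B[seq_along(amps)], amps)) &&
      blk$trial_type[length(amps) + 1L] == "error_clamp"
    if (!ok) note("sequence ", sid, " is not ", paste(amps, collapse = "-"),
                  " force trials followed by one clamp")
  }

  con <- tr[tr$phase == "constant", ]
  if (nrow(con) > 0) {
    if (any(is.na(con$block_id))) {
      note("constant-phase trials must carry a block_id")
    } else {
      sizes <- table(con$block_id)
      if (length(unique(as.integer(sizes))) != 1L)
        note("constant-phase blocks have unequal lengths")
      if (!is.null(cfg) && any(as.integer(sizes) != cfg$block_size))
        note("constant-phase block length differs from configured block_size")
      blkB <- tapply(con$B[con$trial_type == "force_field"],
                     con$block_id[con$trial_type == "force_field"],
                     function(b) length(unique(b)))
      if (any(blkB != 1L)) note("a constant block mixes field amplitudes")
      amp_per_block <- tapply(con$B[con$trial_type == "force_field"],
                              con$block_id[con$trial_type == "force_field"],
                              function(b) b[1L])
      if (!is.null(cfg)) {
        tab <- table(amp_per_block)
        if (!all(as.integer(tab) == 2L) ||
            !setequal(as.numeric(names(tab)), cfg$constant_amplitudes))
          note("each condition amplitude must appear in exactly 2 blocks")
        nclamp <- tapply(con$trial_type, con$block_id,
                         function(tt) sum(tt == "error_clamp"))
        if (any(nclamp != cfg$clamps_per_block))
          note("a constant block has the wrong number of clamps")
        first_of_block <- con[!duplicated(con$block_id), ]
        if (any(first_of_block$trial_type == "error_clamp"))
          note("a constant block starts with an error clamp")
      }
    }
  }
  bad
}

#' Map constant-phase block ids to their field amplitudes
#'
#' @param trials A schedule `trials` tibble (or a session summary carrying
#'   `phase`, `trial_type`, `B`, `block_id` columns).
#' @return Named numeric vector, `names` = block id, values = B (Ns/m).
#' @keywords internal
block_amplitudes <- function(trials) {
  con <- trials[trials$phase == "constant" & trials$trial_type == "force_field", ]
  out <- tapply(con$B, con$block_id, function(b) b[1L])
  stats::setNames(as.numeric(out), names(out))
}

#' Write / read a schedule as CSV
#'
#' One row per trial with columns `index` (0-based), `phase`, `trial_type`,
#' `B`, `sequence_id`, `block_id`; UTF-8, header row, empty cells for NA.
#'
#' @param schedule A `reach_schedule`.
#' @param path Output CSV path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule` returns a
#'   `reach_schedule` (with `config = NULL` — validation against counts then
#'   checks structural invariants only).
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule$trials), path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$sequence_id <- as.integer(df$sequence_id)
  df$block_id <- as.integer(df$block_id)
  structure(list(trials = tibble::as_tibble(df), config = NULL, seed = NA_integer_),
            class = "reach_schedule")
}

#' Read / write a protocol configuration as JSON
#' @param path JSON file path.
#' @param config A `protocol_config` list.
#' @return The configuration (read) or `path`, invisibly (write).
#' @export
read_protocol_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_protocol_config, raw)
}

#' @rdname read_protocol_config
#' @export
write_protocol_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
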