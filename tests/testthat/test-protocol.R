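test_that("default schedule reproduces the published protocol counts", {
  sch <- default_schedule()
  tr <- sch$trials

  expect_equal(nrow(tr), 780L)
  expect_equal(sum(tr$phase == "baseline"), 100L)
  expect_equal(sum(tr$phase == "random"), 200L)
  expect_equal(sum(tr$phase == "constant"), 480L)

  # baseline is all null-field at B = 0
  expect_true(all(tr$trial_type[tr$phase == "baseline"] == "null_field"))
  expect_true(all(tr$B[tr$phase == "baseline"] == 0))

  # 10% of the random phase are clamps, 10 of them sequence-trailing
  rnd <- tr[tr$phase == "random", ]
  expect_equal(sum(rnd$trial_type == "error_clamp"), 20L)
  expect_equal(sum(rnd$trial_type == "error_clamp" & !is.na(rnd$sequence_id)), 10L)
  expect_equal(length(unique(na.omit(tr$sequence_id))), 10L)

  # every sequence is 1-2-3-4 force trials then one clamp, consecutive
  for (sid in 1:10) {
    blk <- tr[!is.na(tr$sequence_id) & tr$sequence_id == sid, ]
    blk <- blk[order(blk$index), ]
    expect_equal(nrow(blk), 5L)
    expect_equal(diff(blk$index), rep(1L, 4))
    expect_equal(blk$trial_type, c(rep("force_field", 4), "error_clamp"))
    expect_equal(blk$B[1:4], c(1, 2, 3, 4))
  }

  # random background amplitudes come from the 7-value set
  bg <- rnd[rnd$trial_type == "force_field" & is.na(rnd$sequence_id), ]
  expect_true(all(bg$B %in% seq(1, 4, by = 0.5)))

  # constant phase: 12 blocks of 40, one amplitude per block, each condition
  # twice, 5 clamps per block (12.5%), never the first trial of a block
  con <- tr[tr$phase == "constant", ]
  expect_equal(length(unique(con$block_id)), 12L)
  expect_true(all(table(con$block_id) == 40L))
  amps <- block_amplitudes <- tapply(
    con$B[con$trial_type == "force_field"],
    con$block_id[con$trial_type == "force_field"], function(b) unique(b))
  expect_true(all(lengths(amps) == 1L))
  expect_equal(sort(as.numeric(unlist(amps))),
               sort(rep(c(1, 2, 2.5, 3, 4, 5), 2)))
  expect_true(all(tapply(con$trial_type, con$block_id,
                         function(tt) sum(tt == "error_clamp")) == 5L))
  firsts <- con[!duplicated(con$block_id), ]
  expect_true(all(firsts$trial_type == "force_field"))
  # 10 clamps per condition amplitude
  blkB <- sapply(amps, identity)
  clamps_per_block <- tapply(con$trial_type, con$block_id,
                             function(tt) sum(tt == "error_clamp"))
  per_cond <- tapply(clamps_per_block, blkB[names(clamps_per_block)], sum)
  expect_true(all(per_cond == 10L))

  expect_length(validate_schedule(sch), 0L)
})

test_that("degenerate and invalid configurations are handled explicitly", {
  cfg0 <- default_protocol_config(n_sequences = 0L, clamp_fraction_random = 0)
  sch0 <- build_schedule(cfg0, seed = 1)
  rnd <- sch0$trials[sch0$trials$phase == "random", ]
  expect_equal(sum(rnd$trial_type == "force_field"), 200L)
  expect_equal(sum(rnd$trial_type == "error_clamp"), 0L)
  expect_length(validate_schedule(sch0), 0L)

  expect_error(build_schedule(default_protocol_config(clamp_fraction_random = 1)),
               "\\[0, 1\\)")
  expect_error(build_schedule(default_protocol_config(clamp_fraction_random = -0.1)),
               "\\[0, 1\\)")
  expect_error(build_schedule(default_protocol_config(n_random = 30L)),
               "sequences")
})

test_that("embed_sequences places disjoint non-adjacent blocks, deterministically", {
  starts <- embed_sequences(200, 10, c(1, 2, 3, 4), seed = 3)
  expect_length(starts, 10L)
  # blocks of length 5, pairwise disjoint with at least one gap trial
  occupied <- unlist(lapply(starts, function(s) s:(s + 4)))
  expect_equal(length(occupied), length(unique(occupied)))
  expect_true(all(diff(sort(starts)) >= 6))
  expect_true(min(starts) >= 1 && max(starts) + 4 <= 200)

  expect_identical(starts, embed_sequences(200, 10, c(1, 2, 3, 4), seed = 3))
  expect_false(identical(starts, embed_sequences(200, 10, c(1, 2, 3, 4), seed = 4)))

  expect_length(embed_sequences(200, 0, c(1, 2, 3, 4), seed = 1), 0L)

  # 40 length-5 blocks need 200 slots plus 39 gaps: infeasible
  expect_error(embed_sequences(200, 40, c(1, 2, 3, 4), seed = 1), "cannot place")
})

test_that("validate_schedule flags corrupted schedules and passes valid ones", {
  sch <- default_schedule()
  expect_length(validate_schedule(sch), 0L)

  bad1 <- sch
  bad1$trials$B[bad1$trials$phase == "baseline"][1] <- 2
  expect_true(any(grepl("baseline", validate_schedule(bad1))))

  bad2 <- sch
  drop_idx <- max(which(bad2$trials$block_id == 1 & !is.na(bad2$trials$block_id)))
  bad2$trials <- bad2$trials[-drop_idx, ]
  rep2 <- validate_schedule(bad2)
  expect_true(any(grepl("block", rep2)))

  bad3 <- sch
  first_seq_force <- which(!is.na(bad3$trials$sequence_id) &
                             bad3$trials$trial_type == "force_field")[1]
  bad3$trials$B[first_seq_force] <- 3.5
  expect_true(any(grepl("sequence", validate_schedule(bad3))))
})

test_that("schedules are deterministic per seed and serialize byte-identically", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_schedule(build_schedule(seed = 11), f1)
  write_schedule(build_schedule(seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))

  f3 <- tempfile(fileext = ".csv")
  write_schedule(build_schedule(seed = 12), f3)
  expect_false(identical(readLines(f1), readLines(f3)))

  back <- read_schedule(f1)
  expect_equal(as.data.frame(back$trials),
               as.data.frame(build_schedule(seed = 11)$trials))
  unlink(c(f1, f2, f3))
})

test_that("config JSON round-trips", {
  cfg <- default_protocol_config(n_sequences = 3L, clamp_fraction_random = 0.2)
  f <- tempfile(fileext = ".json")
  write_protocol_config(cfg, f)
  back <- read_protocol_config(f)
  expect_equal(unclass(back), unclass(cfg))
  unlink(f)
})

test_that("random background amplitudes are uniform over the 7-value set", {
  draws <- unlist(lapply(1:75, function(s) {
    tr <- build_schedule(seed = s)$trials
    bg <- tr[tr$phase == "random" & tr$trial_type == "force_field" &
               is.na(tr$sequence_id), ]
    bg$B
  }))
  expect_gt(length(draws), 10000)
  tab <- table(factor(draws, levels = seq(1, 4, by = 0.5)))
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})
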