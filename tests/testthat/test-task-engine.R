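# Trial composition and event scheduling.

trial_types <- function(sq) vapply(sq, function(t) t$trial_type, integer(1))
trial_matched <- function(sq) vapply(sq, function(t) t$matched, logical(1))

test_that("36-trial 2-Back composition has exact type counts and half matched", {
  sq <- compose_nback(nback_spec(2, 36, seed = 5))
  counts <- table(trial_types(sq))
  expect_equal(as.integer(counts[c("2", "3", "4", "5")]), c(12L, 9L, 9L, 6L))
  expect_equal(sum(trial_matched(sq)), 18L)
})

test_that("smallest valid total follows the same fractions", {
  sq <- compose_nback(nback_spec(1, 12, seed = 2))
  counts <- table(trial_types(sq))
  expect_equal(as.integer(counts[c("1", "2", "3", "4")]), c(4L, 3L, 3L, 2L))
  expect_equal(sum(trial_matched(sq)), 6L)
})

test_that("composition is deterministic and seed-sensitive", {
  spec <- nback_spec(2, 24, seed = 42)
  expect_identical(compose_nback(spec), compose_nback(spec))
  spec2 <- spec; spec2$seed <- 43L
  expect_false(identical(compose_nback(spec), compose_nback(spec2)))
})

test_that("invalid totals are rejected naming the smallest valid total", {
  expect_error(compose_nback(nback_spec(2, 35)), "36")
  expect_error(compose_nback(nback_spec(2, 13)), "24")
  expect_error(compose_nback(nback_spec(2, 36, word_pool = LETTERS[1:6])),
               "pool")
})

test_that("trial structure invariants hold across randomized specs", {
  for (seed in 1:8) {
    n <- sample(1:3, 1)
    sq <- compose_nback(nback_spec(n, 12 * sample(1:3, 1), seed = seed))
    expect_equal(sum(trial_matched(sq)), length(sq) / 2)
    counts <- table(factor(trial_types(sq), levels = n + 0:3))
    expect_equal(as.numeric(counts / length(sq)), c(1/3, 1/4, 1/4, 1/6))
    for (tr in sq) {
      expect_length(tr$displays, tr$trial_type)
      # no word repeats within a trial
      words <- unlist(tr$displays)
      expect_equal(anyDuplicated(words), 0L)
      target <- tr$displays[[tr$trial_type - n + 1L]]
      if (tr$matched) {
        expect_true(tr$probe %in% target)
      } else {
        expect_false(tr$probe %in% target)
      }
    }
    expect_equal(vapply(sq, function(t) t$index, integer(1)),
                 seq_along(sq) - 1L)
  }
})

test_that("timeline places one rest after every twelfth trial", {
  spec <- nback_spec(2, 36, practice_trials = 0, seed = 5)
  tl <- build_timeline(compose_nback(spec), spec)
  rests <- which(tl$kind == "rest")
  expect_length(rests, 3L)
  # rest follows the probe of trials 12, 24, 36 (0-based 11, 23, 35)
  expect_equal(tl$trial_index[rests - 1L], c(11L, 23L, 35L))
  expect_true(all(tl$kind[rests - 1L] == "probe"))
})

test_that("stimulus events keep the 2 s cadence and exact slot onsets", {
  spec <- nback_spec(2, 12, practice_trials = 0, seed = 9)
  sq <- compose_nback(spec)
  tl <- build_timeline(sq, spec)
  stim <- tl[tl$kind %in% c("display", "probe"), ]
  expect_equal(nrow(stim), sum(trial_types(sq)) + length(sq))
  expect_true(all(stim$duration_s == 2))
  # onsets are slot multiples shifted only by completed rests
  rest_before <- vapply(stim$onset_s, function(o) {
    sum(tl$duration_s[tl$kind == "rest" & tl$onset_s < o])
  }, numeric(1))
  expect_true(all((stim$onset_s - rest_before) %% 2 == 0))
})

test_that("a single composed trial schedules displays then probe back to back", {
  spec <- nback_spec(2, 12, practice_trials = 0, seed = 3)
  sq <- compose_nback(spec)
  tl <- build_timeline(sq, spec)
  first <- tl[!is.na(tl$trial_index) & tl$trial_index == 0L, ]
  ty <- sq[[1]]$trial_type
  expect_equal(first$onset_s, seq(0, by = 2, length.out = ty + 1L))
  expect_equal(first$kind, c(rep("display", ty), "probe"))
})

test_that("practice trials precede the block, are flagged, and do not shift rests", {
  spec <- nback_spec(2, 12, practice_trials = 7, seed = 4)
  sq <- compose_nback(spec)
  tl <- build_timeline(sq, spec)
  prac <- vapply(tl$payload, function(p) isTRUE(p$practice), logical(1))
  expect_true(all(which(prac) < min(which(!prac & tl$kind != "rest"))))
  expect_equal(sum(prac & tl$kind == "probe"), 7L)
  expect_true(all(is.na(tl$trial_index[prac])))
  expect_length(which(tl$kind == "rest"), 1L)
})

test_that("timeline event counts follow the composition arithmetic", {
  for (seed in 1:4) {
    spec <- nback_spec(2, 24, practice_trials = 0, seed = seed)
    sq <- compose_nback(spec)
    tl <- build_timeline(sq, spec)
    expect_equal(sum(tl$kind %in% c("display", "probe")),
                 sum(trial_types(sq)) + length(sq))
    expect_equal(sum(tl$kind == "rest"), 24L %/% spec$rest_every)
    # events are sorted and non-overlapping
    expect_false(is.unsorted(tl$onset_s))
    ends <- tl$onset_s + tl$duration_s
    expect_true(all(tl$onset_s[-1] >= ends[-nrow(tl)] - 1e-9))
  }
})

test_that("eyes task alternates cues from the start state", {
  tl <- compose_eyes(eyes_spec(4, interval_s = 30, start_state = "open"))
  expect_equal(tl$onset_s, c(0, 30, 60, 90))
  expect_equal(tl$kind, c("eyes_open_cue", "eyes_close_cue",
                          "eyes_open_cue", "eyes_close_cue"))
  one <- compose_eyes(eyes_spec(1, start_state = "closed"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$kind, "eyes_close_cue")
  expect_identical(compose_eyes(eyes_spec(5, seed = 7)),
                   compose_eyes(eyes_spec(5, seed = 7)))
})

test_that("valence task schedules shuffled images with the three labels", {
  spec <- valence_spec(c("img1", "img2", "img3"), display_duration_s = 6,
                       seed = 11)
  tl <- compose_valence(spec)
  expect_equal(tl$onset_s, c(0, 6, 12))
  expect_equal(tl$kind, rep("image", 3))
  shown <- vapply(tl$payload, function(p) p$image_id, character(1))
  expect_setequal(shown, spec$image_ids)
  expect_identical(compose_valence(spec), compose_valence(spec))
  for (p in tl$payload) {
    expect_identical(p$response_options, c("unpleasant", "neutral", "pleasant"))
  }
  expect_error(valence_spec(character()), "non-empty")
})

test_that("timelines round-trip through JSON", {
  spec <- nback_spec(2, 12, practice_trials = 2, seed = 6)
  tl <- build_timeline(compose_nback(spec), spec)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_timeline(tl, tmp)
  back <- read_timeline(tmp)
  expect_equal(back$onset_s, tl$onset_s)
  expect_equal(back$kind, tl$kind)
  expect_equal(back$trial_index, tl$trial_index)
  for (i in seq_len(nrow(tl))) {
    expect_equal(back$payload[[i]], tl$payload[[i]])
  }
})
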