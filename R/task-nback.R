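# n-Back task composition.
#
# Participants see a series of word pairs ("displays", the potential targets)
# at a fixed cadence, then a single probe word they must match against the
# pair shown n displays earlier. A trial of type n+k shows n+k displays
# before its probe; the composition mixes four trial types (n .. n+3) in
# fixed fractions, with exactly half of all probes matched.

default_word_pool <- function() {
  c("DOG", "CAT", "SUN", "MAP", "KEY", "BOX", "CUP", "HAT", "PEN", "BED",
    "CAR", "BUS", "SEA", "SKY", "EGG", "JAM", "LEG", "ARM", "EYE", "EAR",
    "OAK", "FIG", "OWL", "FOX", "BEE", "ANT", "RAT", "COW", "PIG", "HEN",
    "NET", "ROD", "SAW", "AXE", "NAIL", "ROPE", "LAMP", "DOOR", "WALL", "ROOF")
}

#' Specify an n-Back task
#'
#' Defines the composition of a word n-Back block: `total_trials` trials of
#' four types showing `n`, `n+1`, `n+2` and `n+3` word-pair displays before
#' the probe, mixed in `type_fractions` (defaults 1/3, 1/4, 1/4, 1/6), with
#' exactly half of the probes matched. Displays and probes advance every
#' `stimulus_interval_s` seconds and a white-screen rest of `rest_duration_s`
#' follows every `rest_every`-th trial. `practice_trials` practice trials
#' (excluded from analysis) precede the main block.
#'
#' `total_trials` must make every `fraction * total_trials` an integer
#' (a multiple of 12 under the default fractions); otherwise composition
#' refuses with a message naming the smallest valid total.
#'
#' @param n back distance (positive integer).
#' @param total_trials number of main-block trials.
#' @param stimulus_interval_s seconds per display/probe slot (default 2).
#' @param rest_every insert a rest after every this many main trials.
#' @param rest_duration_s rest duration in seconds.
#' @param practice_trials number of practice trials preceding the block.
#' @param word_pool character vector of stimulus words.
#' @param type_fractions fractions of trials of types `n` .. `n+3`; must sum
#'   to 1 with the outer two fixed at 1/3 and 1/6.
#' @param lure_probability probability that an unmatched probe is a word from
#'   another (non-target) display of the same trial rather than a fresh word.
#' @param seed integer seed governing the whole composition.
#' @return an `nback_spec` object.
#' @examples
#' spec <- nback_spec(n = 2, total_trials = 36, seed = 1)
#' seq <- compose_nback(spec)
#' table(vapply(seq, function(t) t$trial_type, integer(1)))
#' @export
nback_spec <- function(n, total_trials, stimulus_interval_s = 2,
                       rest_every = 12, rest_duration_s = 30,
                       practice_trials = 7,
                       word_pool = default_word_pool(),
                       type_fractions = c(1/3, 1/4, 1/4, 1/6),
                       lure_probability = 0.5, seed = 1L) {
  stopifnot(n >= 1, n == round(n), total_trials >= 1,
            total_trials == round(total_trials),
            stimulus_interval_s > 0, rest_every >= 1, rest_duration_s > 0,
            practice_trials >= 0, length(type_fractions) == 4L,
            lure_probability >= 0, lure_probability <= 1)
  if (abs(sum(type_fractions) - 1) > 1e-9) {
    stop_cs("type_fractions must sum to 1")
  }
  if (abs(type_fractions[1] - 1/3) > 1e-9 || abs(type_fractions[4] - 1/6) > 1e-9) {
    stop_cs("outer type fractions are fixed at 1/3 (type n) and 1/6 (type n+3)")
  }
  structure(list(n = as.integer(n), total_trials = as.integer(total_trials),
                 stimulus_interval_s = stimulus_interval_s,
                 rest_every = as.integer(rest_every),
                 rest_duration_s = rest_duration_s,
                 practice_trials = as.integer(practice_trials),
                 word_pool = as.character(word_pool),
                 type_fractions = type_fractions,
                 matched_fraction = 0.5,
                 lure_probability = lure_probability,
                 seed = as.integer(seed)),
            class = "nback_spec")
}

# Smallest total >= total for which every fraction*total and total/2 are
# integers, searched over multiples of 1.
smallest_valid_total <- function(fractions, total) {
  valid <- function(tt) {
    counts <- fractions * tt
    all(abs(counts - round(counts)) < 1e-9) && tt %% 2 == 0
  }
  tt <- max(2L, as.integer(total))
  while (!valid(tt)) tt <- tt + 1L
  tt
}

validate_nback_counts <- function(spec) {
  counts <- spec$type_fractions * spec$total_trials
  if (any(abs(counts - round(counts)) > 1e-9) || spec$total_trials %% 2 != 0) {
    stop_cs(paste0("total_trials = %d does not yield integer trial-type and ",
                   "matched counts; smallest valid total >= %d is %d"),
            spec$total_trials, spec$total_trials,
            smallest_valid_total(spec$type_fractions, spec$total_trials))
  }
  as.integer(round(counts))
}

# Draw the displays and probe for one trial. `trial_type` is the number of
# displays; the target pair sits n displays before the probe, i.e. display
# trial_type - n + 1 (1-based). Words never repeat within a trial.
compose_one_trial <- function(n, trial_type, matched, pool, lure_probability) {
  need <- 2L * trial_type
  if (length(pool) < need + 1L) {
    stop_cs("word_pool too small: need at least %d words for a %d-display trial",
            need + 1L, trial_type)
  }
  words <- sample(pool, need)
  displays <- split(words, rep(seq_len(trial_type), each = 2L))
  names(displays) <- NULL
  target_idx <- trial_type - n + 1L
  target <- displays[[target_idx]]
  if (matched) {
    probe <- sample(target, 1L)
  } else {
    others <- words[!words %in% target]
    use_lure <- length(others) > 0L && stats::runif(1) < lure_probability
    if (use_lure) {
      probe <- sample(others, 1L)
    } else {
      fresh <- setdiff(pool, words)
      probe <- sample(fresh, 1L)
    }
  }
  list(trial_type = trial_type, displays = displays, probe = probe,
       matched = matched, target_display = target_idx)
}

#' Compose an n-Back trial sequence
#'
#' Produces the ordered main-block trials of an [nback_spec()]: exact
#' per-type counts given by the fractions, exactly `total_trials / 2` matched
#' probes, trial order a seeded uniform shuffle. Deterministic given
#' `spec$seed`.
#'
#' @param spec an `nback_spec`.
#' @return a `trial_sequence`: list of trials, each with `index` (0-based),
#'   `trial_type` (number of displays), `displays` (list of word pairs),
#'   `probe`, `matched`.
#' @export
compose_nback <- function(spec) {
  stopifnot(inherits(spec, "nback_spec"))
  counts <- validate_nback_counts(spec)
  types <- spec$n + 0:3
  if (length(spec$word_pool) < 2L * max(types) + 1L) {
    stop_cs("word_pool too small: need at least %d distinct words",
            2L * max(types) + 1L)
  }
  with_seed(spec$seed, {
    type_vec <- sample(rep(types, counts))
    matched_vec <- logical(spec$total_trials)
    matched_vec[sample.int(spec$total_trials, spec$total_trials / 2L)] <- TRUE
    trials <- vector("list", spec$total_trials)
    for (i in seq_len(spec$total_trials)) {
      tr <- compose_one_trial(spec$n, type_vec[i], matched_vec[i],
                              spec$word_pool, spec$lure_probability)
      tr$index <- i - 1L
      trials[[i]] <- tr
    }
    structure(trials, class = "trial_sequence", n = spec$n)
  })
}

#' @export
print.trial_sequence <- function(x, ...) {
  types <- vapply(x, function(t) t$trial_type, integer(1))
  matched <- vapply(x, function(t) t$matched, logical(1))
  cat(sprintf("<trial_sequence> %d-Back, %d trials (%d matched)\n",
              attr(x, "n"), length(x), sum(matched)))
  print(table(displays = types))
  invisible(x)
}
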