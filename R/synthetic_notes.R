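# Synthetic NOTEEVENTS-like corpora with recorded ground truth.
#
# The generator emulates the structural properties of critical-care note
# tables that the downstream stages must survive: several note types per
# admission, boilerplate sentences replicated within an admission, a PII
# mask token, misspellings/abbreviations, numerals, group-specific signal
# terms, and terms whose per-quarter document prevalence follows a linear
# trend. It never attempts realistic clinical language.

# Base clinical-flavoured lexicon: common words, abbreviations, misspellings.
.base_lexicon <- c(
  "pt", "patient", "stable", "alert", "oriented", "afebrile", "denies",
  "pain", "chest", "abd", "abdomen", "soft", "nontender", "bowel", "sounds",
  "present", "lungs", "clear", "crackles", "bibasilar", "wheeze", "resp",
  "rate", "hr", "bp", "sats", "o2", "nc", "ra", "vent", "intubated",
  "extubated", "trach", "foley", "placed", "removed", "tolerating", "diet",
  "npo", "ivf", "lasix", "given", "held", "morning", "labs", "pending",
  "wbc", "hct", "plt", "creatinine", "bun", "lytes", "repleted", "cxr",
  "ekg", "echo", "ct", "mri", "head", "neg", "positive", "culture", "blood",
  "urine", "sputum", "afib", "sinus", "rhythm", "tachy", "brady", "sbp",
  "map", "neo", "levophed", "weaned", "off", "cont", "continue", "monitor",
  "plan", "goal", "today", "overnight", "family", "meeting", "updated",
  "social", "work", "consult", "ordered", "recieved", "recommed", "assesment",
  "meds", "prn", "tylenol", "morphine", "fentanyl", "versed", "propofol",
  "sedation", "awake", "follows", "commands", "moves", "extremities",
  "edema", "trace", "pedal", "pulses", "palpable", "skin", "intact",
  "breakdown", "sacral", "dressing", "changed", "incision", "cdi", "wound",
  "drain", "output", "adequate", "uop", "amber", "yellow", "gtt", "titrated",
  "insulin", "sliding", "scale", "bs", "glucose", "diabetic", "hx", "pmh",
  "htn", "cad", "chf", "copd", "esrd", "hd", "dialysis", "male", "female",
  "yo", "admitted", "transferred", "micu", "sicu", "ccu", "floor", "unit",
  "room", "air", "mask", "cpap", "peep", "fio2", "abg", "ph", "pco2", "po2",
  "bicarb", "lactate", "trending", "down", "up", "improving", "worsening",
  "unchanged", "overall", "status", "code", "full", "dnr", "dni", "discussed",
  "with", "team", "rounds", "note", "shift", "events", "significant", "none",
  "noted", "at", "this", "time", "will", "follow", "reassess", "pm", "am"
)

#' Configuration for the synthetic note generator
#'
#' All randomness in [generate_cohort()] flows from the single `seed`.
#'
#' @param n_admissions_per_group admissions in each of the two groups
#'   (target, comparison).
#' @param notes_per_admission integer range `c(min, max)` of notes drawn
#'   uniformly per admission.
#' @param background_vocab_size number of distinct background tokens the
#'   lexicon is padded/truncated to.
#' @param signal_terms character vector of tokens injected preferentially
#'   into target-group documents.
#' @param signal_rate_target per-document probability that a given signal
#'   term is injected into a target admission.
#' @param signal_rate_comparison same, for comparison admissions.
#' @param duplicate_fraction fraction of an admission's sentences that are
#'   replicated (each replicated sentence appears at least twice).
#' @param trend_terms data frame with columns `term`, `slope`, `base`:
#'   document prevalence of `term` in quarter q is `base + slope * (q - 1)`,
#'   clamped to \[0, 1\].
#' @param n_quarters number of calendar quarters admissions are spread over.
#' @param digit_noise_rate per-sentence probability of inserting a numeral
#'   token (vitals, years, decimals).
#' @param pii_mask_string literal mask token standing in for de-identified
#'   protected health information.
#' @param age_range admission age range (years) for adult admissions.
#' @param n_underage number of admissions (counted inside the comparison
#'   group) given age < 16, so cohort filtering always has work to do.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_admissions_per_group = 300,
                         notes_per_admission = c(2L, 5L),
                         background_vocab_size = 400,
                         signal_terms = paste0("signalterm", sprintf("%02d", 1:20)),
                         signal_rate_target = 0.6,
                         signal_rate_comparison = 0.05,
                         duplicate_fraction = 0.2,
                         trend_terms = data.frame(
                           term = c("trendup", "trenddown"),
                           slope = c(0.02, -0.02),
                           base = c(0.05, 0.30)
                         ),
                         n_quarters = 8,
                         digit_noise_rate = 0.2,
                         pii_mask_string = "[**PII**]",
                         age_range = c(16, 95),
                         n_underage = 1,
                         seed = 1L) {
  assert_prob(signal_rate_target, "signal_rate_target")
  assert_prob(signal_rate_comparison, "signal_rate_comparison")
  assert_prob(duplicate_fraction, "duplicate_fraction")
  assert_prob(digit_noise_rate, "digit_noise_rate")
  if (background_vocab_size < 10) {
    stopf("configuration error: background_vocab_size must be >= 10")
  }
  if (length(signal_terms) > 0 && signal_rate_target <= signal_rate_comparison) {
    stopf("configuration error: signal_rate_target must exceed signal_rate_comparison")
  }
  if (!is.data.frame(trend_terms) ||
      !all(c("term", "slope", "base") %in% names(trend_terms))) {
    stopf("configuration error: trend_terms needs columns term, slope, base")
  }
  if (n_quarters < 1) stopf("configuration error: n_quarters must be >= 1")
  cfg <- list(
    n_admissions_per_group = as.integer(n_admissions_per_group),
    notes_per_admission = as.integer(notes_per_admission),
    background_vocab_size = as.integer(background_vocab_size),
    signal_terms = as.character(signal_terms),
    signal_rate_target = signal_rate_target,
    signal_rate_comparison = signal_rate_comparison,
    duplicate_fraction = duplicate_fraction,
    trend_terms = trend_terms,
    n_quarters = as.integer(n_quarters),
    digit_noise_rate = digit_noise_rate,
    pii_mask_string = pii_mask_string,
    age_range = age_range,
    n_underage = as.integer(n_underage),
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

.background_vocab <- function(size) {
  vocab <- .base_lexicon
  i <- 2L
  while (length(vocab) < size) {
    vocab <- unique(c(vocab, paste0(.base_lexicon, i)))
    i <- i + 1L
  }
  vocab[seq_len(size)]
}

# one sentence body; extra tokens keep injected sentences distinct
.make_sentence <- function(vocab, weights, len_range = c(4L, 10L),
                           force_tokens = character()) {
  n <- sample(len_range[1]:len_range[2], 1L)
  toks <- sample(vocab, n, replace = TRUE, prob = weights)
  if (length(force_tokens)) {
    pos <- sample(seq_len(n), 1L)
    toks <- append(toks, force_tokens, after = pos)
  }
  paste(toks, collapse = " ")
}

#' Generate a synthetic admission-note cohort with ground truth
#'
#' Produces a notes table (one row per note), a codes table, and a ground
#' truth record of everything that was injected: group labels, per-admission
#' signal terms, per-term trend slopes, and the replicate sentences planted
#' within each admission. One admission with age < 16 (per `n_underage`) and
#' one admission with zero notes (present only in the codes table) are
#' always emitted so cohort filtering is exercised.
#'
#' @param config a [synth_config()].
#' @return list of class `shakespeare_cohort` with elements `notes`
#'   (ADMISSION_ID, AGE, CHARTTIME, CATEGORY, TEXT), `codes`
#'   (ADMISSION_ID, CODE_TYPE, CODE), and `truth`.
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  vocab <- .background_vocab(cfg$background_vocab_size)
  weights <- 1 / seq_along(vocab)          # Zipf-ish token frequencies
  n <- cfg$n_admissions_per_group
  ids <- sprintf("ADM%05d", seq_len(2L * n))
  group <- rep(c("target", "comparison"), each = n)
  names(group) <- ids

  # underage admissions sit at the tail of the comparison group
  age <- sample(cfg$age_range[1]:cfg$age_range[2], 2L * n, replace = TRUE)
  names(age) <- ids
  underage_ids <- character()
  if (cfg$n_underage > 0) {
    underage_ids <- ids[seq(2L * n - cfg$n_underage + 1L, 2L * n)]
    age[underage_ids] <- sample(1:15, cfg$n_underage, replace = TRUE)
  }

  quarter <- sample.int(cfg$n_quarters, 2L * n, replace = TRUE)
  names(quarter) <- ids
  quarter_starts <- seq(as.Date("2006-01-01"), by = "3 months",
                        length.out = cfg$n_quarters)

  categories <- c("Nursing", "Physician", "Radiology", "Discharge summary", "ECG")
  trend <- cfg$trend_terms

  notes_rows <- vector("list", 2L * n)
  truth_signal <- vector("list", 2L * n)
  truth_dup <- vector("list", 2L * n)
  names(truth_signal) <- names(truth_dup) <- ids
  n_pii <- 0L
  total_notes <- 0L

  for (i in seq_along(ids)) {
    id <- ids[i]
    npa <- cfg$notes_per_admission
    k_notes <- if (npa[1] == npa[2]) npa[1] else sample(npa[1]:npa[2], 1L)
    # sentences are (body, has_period) pairs; keys guarantee within-admission
    # uniqueness before duplicates are planted
    seen <- new.env(parent = emptyenv())
    notes <- vector("list", k_notes)
    fresh_sentence <- function(force = character()) {
      for (attempt in 1:50) {
        body <- .make_sentence(vocab, weights, force_tokens = force)
        if (runif(1) < cfg$digit_noise_rate) {
          num <- sample(c("120/80", "98.6", "1.5", "2007", "35", "0.9"), 1L)
          body <- paste(body, num)
        }
        has_period <- runif(1) < 0.75
        key <- .normalize_key(paste0(body, if (has_period) "."))
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          return(list(body = body, period = has_period, key = key))
        }
      }
      stopf("could not generate a distinct sentence after 50 attempts")
    }
    for (j in seq_len(k_notes)) {
      n_sent <- sample(3:8, 1L)
      notes[[j]] <- lapply(seq_len(n_sent), function(s) fresh_sentence())
      # occasional numbered list block (single-unit list items)
      if (runif(1) < 0.15) {
        items <- lapply(1:3, function(s) fresh_sentence())
        for (b in seq_along(items)) {
          items[[b]]$body <- paste0(b, ". ", items[[b]]$body)
          items[[b]]$period <- FALSE
          items[[b]]$list_item <- TRUE
          items[[b]]$key <- .normalize_key(items[[b]]$body)
        }
        notes[[j]] <- c(notes[[j]], items)
      }
    }

    # group signal terms
    rate <- if (group[id] == "target") cfg$signal_rate_target else cfg$signal_rate_comparison
    injected <- character()
    for (s in cfg$signal_terms) {
      if (runif(1) < rate) {
        injected <- c(injected, s)
        j <- sample.int(k_notes, 1L)
        notes[[j]] <- c(notes[[j]], list(fresh_sentence(force = s)))
      }
    }
    truth_signal[[id]] <- injected

    # trend terms: prevalence linear in quarter index
    if (nrow(trend) > 0) {
      for (r in seq_len(nrow(trend))) {
        p <- min(max(trend$base[r] + trend$slope[r] * (quarter[id] - 1L), 0), 1)
        if (runif(1) < p) {
          j <- sample.int(k_notes, 1L)
          notes[[j]] <- c(notes[[j]], list(fresh_sentence(force = trend$term[r])))
        }
      }
    }

    # PII mask token inside ~30% of notes (and every 10th note, so the mask
    # reaches at least 10% of notes even in tiny cohorts); applied to the
    # sentence body before duplicates are planted so replicate copies and
    # their recorded keys stay verbatim-consistent
    masked <- runif(k_notes) < 0.3
    masked[seq(1L, k_notes, by = 10L)] <- TRUE
    for (j in which(masked)) {
      regular <- which(!vapply(notes[[j]], function(x)
        isTRUE(x$list_item), logical(1)))
      s <- regular[sample.int(length(regular), 1L)]
      notes[[j]][[s]]$body <- paste(cfg$pii_mask_string, notes[[j]][[s]]$body)
      notes[[j]][[s]]$key <- .normalize_key(
        paste0(notes[[j]][[s]]$body, if (notes[[j]][[s]]$period) "."))
    }
    n_pii <- n_pii + sum(masked)

    # replicate a fraction of sentences within the admission (verbatim copies,
    # possibly in a different note) and record their keys
    all_sent <- unlist(notes, recursive = FALSE)
    n_dup <- floor(cfg$duplicate_fraction * length(all_sent))
    dup_keys <- character()
    if (n_dup > 0) {
      pick <- sample(seq_along(all_sent), n_dup)
      for (p in pick) {
        copy <- all_sent[[p]]
        j <- sample.int(k_notes, 1L)
        at <- sample.int(length(notes[[j]]) + 1L, 1L) - 1L
        notes[[j]] <- append(notes[[j]], list(copy), after = at)
        dup_keys <- c(dup_keys, copy$key)
      }
    }
    truth_dup[[id]] <- unique(dup_keys)

    # render note text: inline ". ", ".\n", or bare newline separators
    texts <- vapply(notes, function(sent) {
      parts <- vapply(sent, function(x) {
        if (isTRUE(x$list_item)) return(paste0(x$body, "\n"))
        if (x$period) {
          if (runif(1) < 0.5) paste0(x$body, ". ") else paste0(x$body, ".\n")
        } else paste0(x$body, "\n")
      }, character(1))
      sub("[ \n]+$", "", paste(parts, collapse = ""))
    }, character(1))

    total_notes <- total_notes + k_notes

    day0 <- sample(0:40, 1L)
    times <- quarter_starts[quarter[id]] + day0 + seq_len(k_notes) - 1L
    notes_rows[[i]] <- data.frame(
      ADMISSION_ID = id,
      AGE = unname(age[id]),
      CHARTTIME = paste0(format(times, "%Y-%m-%d"), " ",
                         sprintf("%02d:00:00", seq_len(k_notes) %% 24)),
      CATEGORY = sample(categories, k_notes, replace = TRUE),
      TEXT = texts,
      stringsAsFactors = FALSE
    )
  }

  notes <- do.call(rbind, notes_rows)
  rownames(notes) <- NULL

  # codes: target admissions always carry the transfusion-like procedure code
  code_pool <- c("427.31", "584.9", "518.81", "038.9", "V58.61", "96.71")
  codes_rows <- lapply(ids, function(id) {
    k <- sample(1:3, 1L)
    cds <- sample(code_pool, k)
    if (group[id] == "target") cds <- unique(c("99.04", cds))
    data.frame(ADMISSION_ID = id,
               CODE_TYPE = ifelse(grepl("^9", cds), "PROCEDURE", "DIAGNOSIS"),
               CODE = cds, stringsAsFactors = FALSE)
  })
  zero_note_id <- sprintf("ADM%05d", 2L * n + 1L)
  codes_rows[[length(codes_rows) + 1L]] <- data.frame(
    ADMISSION_ID = zero_note_id, CODE_TYPE = "DIAGNOSIS", CODE = "427.31",
    stringsAsFactors = FALSE)
  codes <- do.call(rbind, codes_rows)
  rownames(codes) <- NULL

  truth <- list(
    group = group,
    age = age,
    quarter = quarter,
    quarter_starts = quarter_starts,
    signal_terms = cfg$signal_terms,
    signal_injections = truth_signal,
    trend_terms = trend,
    duplicate_keys = truth_dup,
    underage_admissions = underage_ids,
    zero_note_admission = zero_note_id,
    background_vocab = vocab
  )
  structure(list(notes = notes, codes = codes, truth = truth,
                 config = cfg),
            class = "shakespeare_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Notes and codes as CSV (header row matching the loader schema), ground
#' truth as JSON.
#' @param cohort result of [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "shakespeare_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  notes_path <- file.path(dir, "notes.csv")
  codes_path <- file.path(dir, "codes.csv")
  truth_path <- file.path(dir, "ground_truth.json")
  write.csv(cohort$notes, notes_path, row.names = FALSE)
  write.csv(cohort$codes, codes_path, row.names = FALSE)
  truth <- cohort$truth
  truth$quarter_starts <- format(truth$quarter_starts, "%Y-%m-%d")
  # named vectors must round-trip as JSON objects, not bare arrays
  for (f in c("group", "age", "quarter")) truth[[f]] <- as.list(truth[[f]])
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(notes = notes_path, codes = codes_path, truth = truth_path))
}
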