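TOKEN_FLAGS <- c("filler", "unintelligible", "off_topic", "inaccurate", "non_word")

#' Construct a discourse transcript
#'
#' A transcript is an ordered sequence of annotated tokens from one
#' participant's picture-description response. Token flags carry the
#' annotation judgments (filler, unintelligible, off-topic, inaccurate,
#' non-word) that the CIU counter needs; flags are supplied by human coding
#' or by the synthetic generator, never inferred from text.
#'
#' @param participant_id non-empty identifier.
#' @param tokens data.frame with columns `position` (strictly increasing
#'   integers), `surface` (word as produced), `flags` (string, `|`-separated
#'   subset of the closed flag set, `""` for none), `phrase_id` (integer
#'   phrase index). A zero-row data.frame gives an empty transcript.
#' @return object of class `transcript`.
#' @export
transcript <- function(participant_id, tokens = empty_tokens()) {
  if (!is.character(participant_id) || !nzchar(participant_id))
    stop_invalid("participant_id must be a non-empty string")
  tokens <- as.data.frame(tokens)
  need <- c("position", "surface", "flags", "phrase_id")
  if (!all(need %in% names(tokens)))
    stop_invalid("tokens must have columns: ", paste(need, collapse = ", "))
  tokens <- tokens[need]
  if (nrow(tokens)) {
    if (any(diff(tokens$position) <= 0))
      stop_invalid("token positions must be strictly increasing")
    bad <- setdiff(unlist(strsplit(tokens$flags[nzchar(tokens$flags)], "\\|")),
                   TOKEN_FLAGS)
    if (length(bad))
      stop_invalid("unknown token flags: ", paste(bad, collapse = ", "))
  }
  structure(list(participant_id = participant_id, tokens = tokens),
            class = "transcript")
}

#' @rdname transcript
#' @export
empty_tokens <- function() {
  data.frame(position = integer(), surface = character(),
             flags = character(), phrase_id = integer(),
             stringsAsFactors = FALSE)
}

has_flag <- function(flags, flag) {
  vapply(strsplit(flags, "\\|"), function(f) flag %in% f, logical(1))
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("Transcript %s: %d tokens, %d phrases\n", x$participant_id,
              nrow(x$tokens),
              length(unique(x$tokens$phrase_id))))
  invisible(x)
}

.lemma_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- system.file("extdata", package = "discoursemap")
      irr <- utils::read.delim(file.path(dir, "irregular_forms.tsv"),
                               stringsAsFactors = FALSE)
      ers <- utils::read.delim(file.path(dir, "e_restore.tsv"),
                               stringsAsFactors = FALSE)
      cache <<- list(irregular = stats::setNames(irr$lemma, irr$surface),
                     e_restore = stats::setNames(ers$lemma, ers$stem))
    }
    cache
  }
})

restore_stem <- function(stem, e_restore) {
  hit <- e_restore[stem]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(stem)
  # undouble final consonant (slipp -> slip), but keep -ll/-ss/-ee
  if (n >= 3) {
    last2 <- substr(stem, n - 1, n)
    c1 <- substr(last2, 1, 1)
    if (c1 == substr(last2, 2, 2) && !c1 %in% c("l", "s", "e"))
      return(substr(stem, 1, n - 1))
  }
  stem
}

#' Normalize a surface token to its lemma
#'
#' Deterministic rule-based lemmatizer: lower-case, strip surrounding
#' punctuation and possessive `'s`, look the form up in a packaged
#' irregular-form table, then apply ordered suffix-stripping rules
#' (`-ies` to `-y`, `-es` after sibilants, `-s`, `-ing` with e-restoration
#' and consonant undoubling, `-ed` likewise). Returns the cleaned surface
#' unchanged when no rule applies. The irregular and e-restoration tables
#' live in `extdata/` and can be extended with user rows via `extra_irregular`.
#'
#' @param surface character vector of non-empty word tokens.
#' @param extra_irregular optional named character vector (surface -> lemma)
#'   consulted before the packaged table.
#' @return character vector of lemmas.
#' @export
#' @examples
#' normalize_token(c("cookie", "stealing", "children", "Cookies!"))
normalize_token <- function(surface, extra_irregular = NULL) {
  if (length(surface) == 0) return(character())
  if (any(!nzchar(surface)))
    stop_invalid("surface forms must be non-empty")
  tabs <- .lemma_tables()
  vapply(surface, function(w) {
    w <- tolower(w)
    w <- gsub("^[^a-z']+|[^a-z']+$", "", w)
    w <- sub("'s$", "", w)
    w <- gsub("'", "", w)
    if (!nzchar(w)) return(w)
    if (!is.null(extra_irregular) && !is.na(extra_irregular[w]))
      return(unname(extra_irregular[w]))
    irr <- tabs$irregular[w]
    if (!is.na(irr)) return(unname(irr))
    n <- nchar(w)
    if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
    if (n > 3 && endsWith(w, "es") &&
        grepl("(s|x|z|ch|sh)es$", w)) return(substr(w, 1, n - 2))
    if (n > 3 && endsWith(w, "s") && !endsWith(w, "ss"))
      return(substr(w, 1, n - 1))
    if (n > 4 && endsWith(w, "ing"))
      return(restore_stem(substr(w, 1, n - 3), tabs$e_restore))
    if (n > 4 && endsWith(w, "ed"))
      return(restore_stem(substr(w, 1, n - 2), tabs$e_restore))
    w
  }, character(1), USE.NAMES = FALSE)
}

# map a normalized form to (item_id, kind) under a checklist; NA if no match
build_match_table <- function(checklist) {
  ids <- checklist$items$item_id
  lem <- stats::setNames(ids, checklist$items$lemma)
  syn <- stats::setNames(rep(ids, lengths(checklist$synonyms[ids])),
                         unlist(checklist$synonyms[ids]))
  list(lemma = lem, synonym = syn)
}

#' Score a transcript for Content Word Fluency
#'
#' Applies the CWF coding rule: one point every time the participant produces
#' a checklist item -- in base form, any inflected form, or as a listed
#' synonym (synonyms are themselves normalized before lookup) -- excluding
#' immediate repetitions and perseverations of the same item. Adjacency for
#' the repetition rule is evaluated after skipping filler-flagged tokens
#' only; a repeat separated by any contentful token, or occurring in a later
#' phrase, counts again. A perseveration is the third or later consecutive
#' resolution to one item within a phrase. Unintelligible tokens never match.
#'
#' @param transcript a [transcript()].
#' @param checklist a [checklist()].
#' @return object of class `cwf_result`: list with `participant_id`,
#'   `per_item_counts` (named integer vector over all checklist items),
#'   `total`, `audit` (data.frame position/item_id/match_kind), and
#'   `excluded` (data.frame position/reason).
#' @export
score_cwf <- function(transcript, checklist) {
  stopifnot(inherits(transcript, "transcript"), inherits(checklist, "cwf_checklist"))
  mt <- build_match_table(checklist)
  tok <- transcript$tokens
  audit <- list(); excluded <- list()
  # state: resolution of the last non-filler token (NA item if it didn't match)
  prev_item <- NA_character_; prev_phrase <- NA_integer_; run <- 0L
  for (i in seq_len(nrow(tok))) {
    fl <- tok$flags[i]
    if (has_flag(fl, "filler")) next                     # transparent
    item <- NA_character_; kind <- NA_character_
    if (!has_flag(fl, "unintelligible")) {
      norm <- normalize_token(tok$surface[i])
      if (nzchar(norm)) {
        if (!is.na(mt$lemma[norm])) {
          item <- unname(mt$lemma[norm])
          clean <- gsub("[^a-z']", "", tolower(tok$surface[i]))
          kind <- if (identical(clean, norm)) "lemma" else "inflected"
        } else {
          syn_norm <- norm
          hit <- mt$synonym[syn_norm]
          if (is.na(hit)) {
            # inflected synonym: normalize the synonym inventory lazily
            syn_lemmas <- normalize_token(names(mt$synonym))
            idx <- match(syn_norm, syn_lemmas)
            if (!is.na(idx)) hit <- mt$synonym[idx]
          }
          if (!is.na(hit)) { item <- unname(hit); kind <- "synonym" }
        }
      }
    }
    if (is.na(item)) {
      prev_item <- NA_character_; run <- 0L
      prev_phrase <- tok$phrase_id[i]
      next
    }
    same_run <- identical(item, prev_item) &&
      identical(tok$phrase_id[i], prev_phrase)
    run <- if (same_run) run + 1L else 1L
    if (run == 1L) {
      audit[[length(audit) + 1L]] <-
        data.frame(position = tok$position[i], item_id = item,
                   match_kind = kind, stringsAsFactors = FALSE)
    } else {
      reason <- if (run == 2L) "immediate_repetition" else "perseveration"
      excluded[[length(excluded) + 1L]] <-
        data.frame(position = tok$position[i], reason = reason,
                   stringsAsFactors = FALSE)
    }
    prev_item <- item; prev_phrase <- tok$phrase_id[i]
  }
  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(position = integer(), item_id = character(),
               match_kind = character(), stringsAsFactors = FALSE)
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(position = integer(), reason = character(), stringsAsFactors = FALSE)
  counts <- table(factor(audit$item_id, levels = checklist$items$item_id))
  counts <- stats::setNames(as.integer(counts), checklist$items$item_id)
  structure(list(participant_id = transcript$participant_id,
                 per_item_counts = counts, total = sum(counts),
                 audit = audit, excluded = excluded),
            class = "cwf_result")
}

#' @export
print.cwf_result <- function(x, ...) {
  cat(sprintf("CWF score for %s: %d (%d matches audited, %d exclusions)\n",
              x$participant_id, x$total, nrow(x$audit), nrow(x$excluded)))
  invisible(x)
}

#' Count Correct Information Units
#'
#' A token counts as a CIU when it carries none of the exclusion flags
#' (filler, unintelligible, off-topic, inaccurate, non-word) and is not an
#' immediate repetition -- same normalized form as the preceding unflagged
#' token, adjacency evaluated after removing all flagged tokens. Relevance
#' and accuracy judgments are annotation-driven; the counter is
#' deterministic given the flags.
#'
#' @param transcript a [transcript()].
#' @return integer CIU count.
#' @export
count_cius <- function(transcript) {
  tok <- transcript$tokens
  if (!nrow(tok)) return(0L)
  clean <- !Reduce(`|`, lapply(TOKEN_FLAGS, function(f) has_flag(tok$flags, f)))
  surf <- tok$surface[clean]
  if (!length(surf)) return(0L)
  norm <- normalize_token(surf)
  keep <- c(TRUE, norm[-1] != norm[-length(norm)])
  sum(keep)
}

#' Count words in a transcript
#'
#' Tokens not flagged unintelligible or non-word; fillers count as words.
#'
#' @param transcript a [transcript()].
#' @return integer word count.
#' @export
word_count <- function(transcript) {
  tok <- transcript$tokens
  if (!nrow(tok)) return(0L)
  sum(!(has_flag(tok$flags, "unintelligible") | has_flag(tok$flags, "non_word")))
}

#' Build a persons-by-items response matrix from CWF results
#'
#' Dichotomizes per-item counts (produced at least once = 1) into the matrix
#' that the item-response models consume. With `for_irt = TRUE`, columns
#' with no variance (all-zero or all-one) are dropped and reported, since a
#' dichotomous IRT model cannot estimate parameters for them. The study data
#' this mirrors retained 17 of 22 checklist items after such degeneracy
#' filtering; the exact exclusion rule used there is not published, so the
#' no-variance drop is this package's reconstruction.
#'
#' @param results list of `cwf_result`, all scored against `checklist`.
#' @param checklist the shared [checklist()].
#' @param for_irt drop degenerate columns and flag the matrix irt-ready.
#' @return object of class `irt_matrix`: list with `persons`, `items`,
#'   `data` (0/1 matrix), `irt_ready`, `dropped_items`.
#' @export
response_matrix <- function(results, checklist, for_irt = FALSE) {
  if (!length(results)) stop_invalid("`results` must be a non-empty list")
  ids <- checklist$items$item_id
  data <- t(vapply(results, function(r) {
    if (!identical(names(r$per_item_counts), ids))
      stop_invalid("all results must be scored against the same checklist")
    as.integer(r$per_item_counts >= 1L)
  }, integer(length(ids))))
  colnames(data) <- ids
  rownames(data) <- vapply(results, `[[`, character(1), "participant_id")
  dropped <- character()
  if (for_irt) {
    cm <- colMeans(data)
    degenerate <- cm == 0 | cm == 1
    dropped <- ids[degenerate]
    data <- data[, !degenerate, drop = FALSE]
  }
  irt_matrix(data, irt_ready = for_irt, dropped_items = dropped)
}

#' Construct an item-response matrix container
#'
#' @param data binary persons x items matrix with dimnames.
#' @param irt_ready whether degenerate columns have been removed.
#' @param dropped_items ids of columns removed upstream.
#' @return object of class `irt_matrix`.
#' @export
irt_matrix <- function(data, irt_ready = FALSE, dropped_items = character()) {
  data <- as.matrix(data)
  if (!all(data %in% c(0L, 1L))) stop_invalid("entries must be 0/1")
  if (is.null(colnames(data))) colnames(data) <- paste0("item", seq_len(ncol(data)))
  if (is.null(rownames(data))) rownames(data) <- paste0("p", seq_len(nrow(data)))
  if (irt_ready && ncol(data)) {
    cm <- colMeans(data)
    if (any(cm == 0 | cm == 1))
      stop_invalid("irt-ready matrix may not contain all-0/all-1 columns")
  }
  structure(list(persons = rownames(data), items = colnames(data),
                 data = data, irt_ready = irt_ready,
                 dropped_items = dropped_items),
            class = "irt_matrix")
}

#' Read a transcript from token-per-line TSV
#'
#' Expected columns: `position`, `surface`, `flags` (`|`-separated, empty for
#' none), `phrase_id`. The participant id defaults to the file stem.
#'
#' @param path TSV file.
#' @param participant_id optional id override.
#' @return a [transcript()].
#' @export
read_transcript_tsv <- function(path, participant_id = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(surface = "character", flags = "character"),
                           na.strings = NULL)
  tab$flags[is.na(tab$flags)] <- ""
  transcript(participant_id %||% sub("\\.[^.]*$", "", basename(path)), tab)
}

#' Write a transcript as token-per-line TSV
#'
#' @param x a [transcript()].
#' @param path output file.
#' @export
write_transcript_tsv <- function(x, path) {
  utils::write.table(x$tokens, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CHAT-lite transcript
#'
#' Minimal dialect of CHAT-style transcription: one utterance per line
#' (each line becomes one phrase), `&-` prefixed tokens are fillers, `xxx`
#' is an unintelligible token, and a `[x N]` marker repeats the preceding
#' token N times in total (the extra copies are literal immediate repeats).
#' Lines starting with `%` or `@` are ignored as metadata.
#'
#' @param path text file.
#' @param participant_id optional id override.
#' @return a [transcript()].
#' @export
read_transcript_chat <- function(path, participant_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[%@]", lines) & nzchar(trimws(lines))]
  pos <- 0L
  rows <- list()
  for (ph in seq_along(lines)) {
    words <- strsplit(trimws(lines[ph]), "\\s+")[[1]]
    i <- 1L
    while (i <= length(words)) {
      w <- words[i]
      if (grepl("^\\[x", w) && i > 1L) {
        n <- as.integer(gsub("\\D", "", paste(w, if (!grepl("\\]", w)) words[i + 1L])))
        last <- rows[[length(rows)]]
        for (k in seq_len(max(n - 1L, 0L))) {
          pos <- pos + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            position = pos, surface = last$surface, flags = last$flags,
            phrase_id = ph, stringsAsFactors = FALSE)
        }
        i <- i + if (grepl("\\]", w)) 1L else 2L
        next
      }
      flags <- ""
      surf <- w
      if (startsWith(w, "&-")) { flags <- "filler"; surf <- substring(w, 3) }
      if (surf == "xxx") flags <- "unintelligible"
      pos <- pos + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, surface = surf, flags = flags, phrase_id = ph,
        stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  tok <- if (length(rows)) do.call(rbind, rows) else empty_tokens()
  transcript(participant_id %||% sub("\\.[^.]*$", "", basename(path)), tok)
}
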