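#' Construct a content-word-fluency checklist
#'
#' A checklist is the stimulus-specific list of target content words against
#' which spoken-discourse samples are scored. Each item carries a lemma, an
#' optional synonym set, and psycholinguistic covariates (word class,
#' phoneme length, log per-million lemma frequency, imageability rating)
#' used by the psycholinguistic regression.
#'
#' Invariants enforced: item ids and lemmas unique; a lemma never appears in
#' its own (or any) synonym set; synonym sets are pairwise disjoint across
#' items, so every surface form resolves to at most one item.
#'
#' @param items data.frame with columns `item_id`, `lemma`, `word_class`
#'   (`"noun"` or `"verb"`), `length_phonemes`, `frequency`, `imageability`.
#' @param synonyms named list mapping `item_id` to a character vector of
#'   synonym lemmas (may be empty or omitted for an item).
#' @param stimulus_name name of the eliciting picture/stimulus.
#' @return an object of class `cwf_checklist`.
#' @export
checklist <- function(items, synonyms = list(), stimulus_name = "synthetic-scene") {
  required <- c("item_id", "lemma", "word_class", "length_phonemes",
                "frequency", "imageability")
  if (!is.data.frame(items) || !all(required %in% names(items)))
    stop_invalid("`items` must contain columns: ", paste(required, collapse = ", "))
  items <- as.data.frame(items)[required]
  items$item_id <- as.character(items$item_id)
  items$lemma <- as.character(items$lemma)
  if (anyDuplicated(items$item_id)) stop_invalid("item ids must be unique")
  if (anyDuplicated(items$lemma)) stop_invalid("no two items may share a lemma")
  if (!all(items$word_class %in% c("noun", "verb")))
    stop_invalid("word_class must be 'noun' or 'verb'")
  if (any(items$length_phonemes < 1)) stop_invalid("length_phonemes must be >= 1")
  syn <- lapply(items$item_id, function(id) {
    s <- unique(as.character(synonyms[[id]] %||% character()))
    s[nzchar(s)]
  })
  names(syn) <- items$item_id
  all_syn <- unlist(syn, use.names = FALSE)
  if (anyDuplicated(all_syn))
    stop_invalid("synonym sets must be pairwise disjoint across items")
  if (length(intersect(all_syn, items$lemma)))
    stop_invalid("a synonym may not duplicate any item lemma")
  structure(list(items = items, synonyms = syn, stimulus_name = stimulus_name),
            class = "cwf_checklist")
}

#' @export
print.cwf_checklist <- function(x, ...) {
  cat(sprintf("CWF checklist '%s': %d items (%d nouns, %d verbs), %d synonyms\n",
              x$stimulus_name, nrow(x$items),
              sum(x$items$word_class == "noun"),
              sum(x$items$word_class == "verb"),
              length(unlist(x$synonyms))))
  invisible(x)
}

#' Read a checklist from JSON or TSV
#'
#' JSON layout: `{stimulus_name, items: [{item_id, lemma, synonyms, word_class,
#' length_phonemes, frequency, imageability}, ...]}`. TSV layout: one item per
#' row with a `synonyms` column holding `|`-separated lemmas. Frequencies are
#' expected as log10 per-million counts (log-scaled upstream on load).
#'
#' @param path file path ending in `.json` or `.tsv`.
#' @return a `cwf_checklist`.
#' @export
read_checklist <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    items <- as.data.frame(raw$items)
    syn_col <- raw$items$synonyms %||% lapply(seq_len(nrow(items)), function(i) character())
    if (is.character(syn_col)) syn_col <- strsplit(syn_col, "\\|")
    synonyms <- stats::setNames(syn_col, items$item_id)
    checklist(items[setdiff(names(items), "synonyms")], synonyms,
              raw$stimulus_name %||% "unnamed")
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    synonyms <- stats::setNames(strsplit(tab$synonyms %||% rep("", nrow(tab)), "\\|"),
                                tab$item_id)
    checklist(tab[setdiff(names(tab), "synonyms")], synonyms)
  }
}

#' Write a checklist to JSON
#'
#' @param x a `cwf_checklist`.
#' @param path output path.
#' @export
write_checklist <- function(x, path) {
  items <- x$items
  items$synonyms <- vapply(x$synonyms[items$item_id],
                           function(s) paste(s, collapse = "|"), character(1))
  jsonlite::write_json(list(stimulus_name = x$stimulus_name, items = items),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
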