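# shared fixtures: a tiny checklist and a token-table builder

tiny_checklist <- function() {
  checklist(
    data.frame(item_id = c("cookie", "steal", "fall"),
               lemma = c("cookie", "steal", "fall"),
               word_class = c("noun", "verb", "verb"),
               length_phonemes = c(4, 4, 3),
               frequency = c(3.1, 2.2, 2.5),
               imageability = c(600, 410, 430),
               stringsAsFactors = FALSE),
    synonyms = list(steal = "take"))
}

make_transcript <- function(words, flags = "", phrase = 1L, id = "p1") {
  n <- length(words)
  transcript(id, data.frame(
    position = seq_len(n), surface = words,
    flags = rep_len(flags, n), phrase_id = rep_len(as.integer(phrase), n),
    stringsAsFactors = FALSE))
}

# Rasch-simulated irt-ready matrix with known difficulties
rasch_fixture <- function(n = 200, k = 10, seed = 42, slope = 1,
                          b_sd = 1, theta = NULL) {
  b <- discoursemap:::with_seed(seed, stats::rnorm(k, 0, b_sd))
  names(b) <- sprintf("it%02d", seq_len(k))
  if (is.null(theta))
    theta <- discoursemap:::with_seed(seed + 1, stats::rnorm(n))
  Y <- simulate_irt_responses(theta, b, slope = slope, seed = seed + 2)
  list(Y = Y, b = b, theta = theta)
}

# small lesion cohort on a toy grid from hand-built volumes
toy_volume <- function(grid, voxels, voxel_size = 2) {
  arr <- array(0, dim = grid)
  arr[voxels] <- 1
  lesion_volume(arr, voxel_size_mm = voxel_size)
}
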