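#' @name synthdata
#' @title Synthetic cohort generator
#'
#' @description
#' Generates complete synthetic study cohorts -- checklist, annotated
#' transcripts, connected lesion blobs on a shared grid, a box-shaped tract
#' atlas, a streamline template and a behaviour table -- with the
#' statistical structure the downstream analyses assume: item production
#' follows a Rasch (1PL) model over a latent ability, ability is depressed
#' in proportion to lesion load in a designated critical region, transcripts
#' embed produced items among fillers, inflections, synonyms, immediate
#' repetitions and extra stimulus-relevant words (so CIU counts exceed CWF
#' scores), and one atlas tract overlaps the critical region. Everything is
#' deterministic given the configuration seed.
NULL

# synthetic scene vocabulary: lemma, class, phoneme length, synonyms
.word_pool <- function() {
  n <- function(lemma, len, syn = "") list(lemma = lemma, class = "noun",
                                           len = len, syn = syn)
  v <- function(lemma, len, syn = "") list(lemma = lemma, class = "verb",
                                           len = len, syn = syn)
  list(
    n("cookie", 4, "biscuit"), n("jar", 3), n("stool", 4), n("boy", 3, "lad"),
    n("girl", 3, "lass"), n("mother", 4, "mum|mom"), n("child", 4, "kid"),
    n("sink", 4), n("water", 4), n("window", 5), n("curtain", 5, "drape"),
    n("dish", 3), n("plate", 4), n("cup", 3, "mug"), n("towel", 4),
    n("cabinet", 7), n("counter", 6), n("kitchen", 5), n("floor", 3),
    n("garden", 5, "yard"),
    v("steal", 4, "take|grab|swipe"), v("fall", 3, "tip|topple"),
    v("wash", 3, "clean|rinse"), v("dry", 3, "wipe"),
    v("overflow", 6, "spill"), v("reach", 3), v("stand", 5), v("climb", 4),
    v("drop", 4), v("pour", 3), v("splash", 4)
  )
}

.filler_pool <- c("uh", "um", "er", "hmm", "well", "like")
.context_pool <- c("the", "a", "and", "is", "was", "then", "there", "here",
                   "on", "under", "busy", "wet", "messy", "outside",
                   "because", "while", "again", "almost", "nearly", "about")
.offtopic_pool <- c("weather", "lunch", "holiday", "television")
.nonword_pool <- c("flib", "wug", "blick")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort. Defaults are the package's
#' reference study conditions: 100 participants, a 22-item checklist, a
#' 32x32x32 grid at 2 mm voxels (a desk-scale stand-in for template space),
#' a critical region inside the synthetic frontal-aslant tract, ability
#' decrement 1.5 per unit lesion load, ability noise SD 0.8, filler rate
#' 0.15 and immediate-repetition rate 0.08.
#'
#' @param n_participants cohort size (>= 0).
#' @param n_items checklist length (>= 1).
#' @param grid_shape 3 positive integers.
#' @param voxel_size_mm positive voxel edge length.
#' @param critical_region 1-based linear voxel indices whose lesion load
#'   depresses ability; `NULL` selects the default region inside the FAT
#'   box of [generate_tract_atlas()].
#' @param effect_beta ability decrement per unit critical-region load.
#' @param noise_sd SD of the ability noise term (> 0 unless exactly 0 is
#'   wanted for deterministic checks).
#' @param filler_rate,repetition_rate probabilities in `[0, 1]`.
#' @param seed integer master seed; identical configs give byte-identical
#'   cohorts.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 100, n_items = 22,
                              grid_shape = c(32, 32, 32), voxel_size_mm = 2,
                              critical_region = NULL, effect_beta = 1.5,
                              noise_sd = 0.8, filler_rate = 0.15,
                              repetition_rate = 0.08, seed = 1) {
  n_participants <- assert_count(n_participants, "n_participants")
  n_items <- assert_count(n_items, "n_items", min = 1L)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 4))
    stop_invalid("grid_shape must be 3 integers >= 4")
  if (voxel_size_mm <= 0) stop_invalid("voxel_size_mm must be positive")
  filler_rate <- assert_prob(filler_rate, "filler_rate")
  repetition_rate <- assert_prob(repetition_rate, "repetition_rate")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (is.null(critical_region))
    critical_region <- default_critical_region(grid_shape)
  critical_region <- sort(unique(as.integer(critical_region)))
  if (length(critical_region) == 0 && effect_beta != 0)
    stop_invalid("empty critical_region with a non-zero effect_beta")
  if (length(critical_region) &&
      (min(critical_region) < 1 || max(critical_region) > prod(grid_shape)))
    stop_invalid("critical_region indices outside the grid")
  structure(list(n_participants = n_participants, n_items = n_items,
                 grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 critical_region = critical_region, effect_beta = effect_beta,
                 noise_sd = noise_sd, filler_rate = filler_rate,
                 repetition_rate = repetition_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

box_voxels <- function(grid, fx, fy, fz) {
  rng <- function(f, g) max(1L, ceiling(f[1] * g)):min(g, ceiling(f[2] * g))
  idx <- expand.grid(x = rng(fx, grid[1]), y = rng(fy, grid[2]),
                     z = rng(fz, grid[3]))
  sort((idx$z - 1L) * grid[1] * grid[2] + (idx$y - 1L) * grid[1] + idx$x)
}

#' Synthetic tract atlas
#'
#' Eight named box-shaped stand-ins for language-relevant tracts (FAT, AF,
#' three SLF branches, IFOF, ILF, UF), deterministically placed by
#' fractional grid coordinates. No anatomical realism is intended; the
#' boxes give the tract-level analyses named, partially overlapping voxel
#' sets with the right topology (the default critical region sits inside
#' FAT).
#'
#' @param grid_shape 3 positive integers.
#' @return a [tract_atlas()].
#' @export
generate_tract_atlas <- function(grid_shape) {
  g <- as.integer(grid_shape)
  tract_atlas(list(
    FAT  = box_voxels(g, c(0.22, 0.38), c(0.55, 0.75), c(0.55, 0.72)),
    AF   = box_voxels(g, c(0.30, 0.50), c(0.35, 0.58), c(0.48, 0.62)),
    SLF1 = box_voxels(g, c(0.32, 0.62), c(0.42, 0.70), c(0.76, 0.86)),
    SLF2 = box_voxels(g, c(0.32, 0.62), c(0.42, 0.70), c(0.64, 0.73)),
    SLF3 = box_voxels(g, c(0.32, 0.62), c(0.42, 0.70), c(0.52, 0.60)),
    IFOF = box_voxels(g, c(0.25, 0.70), c(0.28, 0.48), c(0.40, 0.50)),
    ILF  = box_voxels(g, c(0.48, 0.78), c(0.22, 0.44), c(0.34, 0.45)),
    UF   = box_voxels(g, c(0.18, 0.40), c(0.24, 0.44), c(0.34, 0.47))
  ), g)
}

#' @rdname generate_tract_atlas
#' @param n_voxels size of the default critical region (default 20).
#' @export
default_critical_region <- function(grid_shape, n_voxels = 20) {
  g <- as.integer(grid_shape)
  fat <- generate_tract_atlas(g)$tracts$FAT
  co <- arrayInd(fat, g)
  ctr <- colMeans(co)
  # compact ball of voxels nearest the tract centroid
  d2 <- rowSums(sweep(co, 2, ctr)^2)
  sort(fat[order(d2)[seq_len(min(n_voxels, length(fat)))]])
}

#' Generate a synthetic CWF checklist
#'
#' Samples `n_items` items from a packaged synthetic scene vocabulary
#' (nouns and verbs with synonym sets), keeping roughly the 15:7
#' noun-to-verb ratio of published checklists, and draws item difficulties
#' from a standard normal (stored as the `true_difficulties` attribute,
#' named by item id). Psycholinguistic covariates span the published
#' ranges: phoneme length 2-7, log frequency 0.77-4.56, imageability
#' 230-638. Requests beyond the pool size are padded with pseudo-lemmas.
#'
#' @param n_items number of items (>= 1).
#' @param seed integer seed.
#' @return a [checklist()] with attribute `true_difficulties`.
#' @export
generate_checklist <- function(n_items, seed = 1) {
  n_items <- assert_count(n_items, "n_items", min = 1L)
  pool <- .word_pool()
  with_seed(child_seed(seed, 1), {
    classes <- vapply(pool, `[[`, character(1), "class")
    n_nouns <- min(sum(classes == "noun"), round(n_items * 15 / 22))
    n_verbs <- min(sum(classes == "verb"), n_items - n_nouns)
    pick <- c(sample(which(classes == "noun"), n_nouns),
              sample(which(classes == "verb"), n_verbs))
    chosen <- pool[pick]
    extra <- n_items - length(chosen)
    if (extra > 0)
      chosen <- c(chosen, lapply(seq_len(extra), function(i)
        list(lemma = sprintf("zorp%02d", i),
             class = if (i %% 2) "noun" else "verb",
             len = sample(2:7, 1), syn = "")))
    items <- data.frame(
      item_id = sprintf("it%02d", seq_len(n_items)),
      lemma = vapply(chosen, `[[`, character(1), "lemma"),
      word_class = vapply(chosen, `[[`, character(1), "class"),
      length_phonemes = pmin(7L, pmax(2L, vapply(chosen, function(x)
        as.integer(x$len), integer(1)))),
      frequency = round(stats::runif(n_items, 0.77, 4.56), 2),
      imageability = round(stats::runif(n_items, 230, 638), 1),
      stringsAsFactors = FALSE)
    synonyms <- stats::setNames(lapply(chosen, function(x) {
      s <- strsplit(x$syn, "\\|")[[1]]
      s[nzchar(s)]
    }), items$item_id)
    # each item keeps 0-3 synonyms
    synonyms <- lapply(synonyms, function(s) utils::head(s, 3))
    b <- stats::rnorm(n_items)
    cl <- checklist(items, synonyms, stimulus_name = "synthetic-kitchen-scene")
    attr(cl, "true_difficulties") <- stats::setNames(b, items$item_id)
    cl
  })
}

# connected lesion blob emulating a vascular-territory stroke: the primary
# seed voxel is drawn around the territory centre, a satellite seed nearby,
# and growth proceeds by randomized 6-neighbour frontier accretion with
# partial acceptance (irregular boundaries) to a log-normal target size
grow_lesion_blob <- function(grid, target, seed, territory_center = NULL,
                             territory_sd = 3, accept = 0.4, n_seeds = 2) {
  with_seed(seed, {
    nvox <- prod(grid)
    target <- min(max(target, 1L), floor(nvox * 0.4))
    if (is.null(territory_center)) territory_center <- grid / 2
    clamp <- function(x, g) pmin(pmax(round(x), 1L), g)
    lin <- function(co) (co[, 3] - 1L) * grid[1] * grid[2] +
      (co[, 2] - 1L) * grid[1] + co[, 1]
    starts <- matrix(0L, n_seeds, 3)
    starts[1, ] <- vapply(1:3, function(d)
      clamp(stats::rnorm(1, territory_center[d], territory_sd), grid[d]),
      numeric(1))
    if (n_seeds > 1) for (s in 2:n_seeds)
      starts[s, ] <- vapply(1:3, function(d)
        clamp(stats::rnorm(1, starts[1, d], 3), grid[d]), numeric(1))
    mask <- array(FALSE, dim = grid)
    mask[lin(starts)] <- TRUE
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    frontier <- starts
    size <- nrow(unique(starts))
    while (size < target && nrow(frontier) > 0) {
      cand <- do.call(rbind, lapply(seq_len(6), function(o)
        sweep(frontier, 2, offs[o, ], `+`)))
      ok <- cand[, 1] >= 1 & cand[, 1] <= grid[1] &
        cand[, 2] >= 1 & cand[, 2] <= grid[2] &
        cand[, 3] >= 1 & cand[, 3] <= grid[3]
      cand <- unique(cand[ok, , drop = FALSE])
      cand <- cand[!mask[lin(cand)], , drop = FALSE]
      if (!nrow(cand)) break
      keep <- stats::runif(nrow(cand)) < accept
      if (!any(keep)) keep[sample.int(nrow(cand), 1)] <- TRUE
      add <- cand[keep, , drop = FALSE]
      add <- add[sample.int(nrow(add)), , drop = FALSE]
      takeN <- min(nrow(add), target - size)
      add <- add[seq_len(takeN), , drop = FALSE]
      mask[lin(add)] <- TRUE
      size <- size + takeN
      frontier <- add
    }
    mask
  })
}

inflect_surface <- function(lemma, word_class) {
  suffix <- if (word_class == "noun") "s" else sample(c("s", "ing", "ed"), 1)
  surf <- if (suffix == "s") {
    if (grepl("(s|x|z|ch|sh)$", lemma)) paste0(lemma, "es") else paste0(lemma, "s")
  } else {
    stem <- sub("e$", "", lemma)
    paste0(stem, suffix)
  }
  # self-check: only emit inflections the normalizer provably inverts
  if (identical(normalize_token(surf), lemma)) surf else lemma
}

assemble_transcript <- function(pid, produced_items, checklist, config, seed) {
  with_seed(seed, {
    items <- checklist$items
    rows <- list(); pos <- 0L; phrase <- 1L; in_phrase <- 0L
    emit <- function(surface, flags = "") {
      pos <<- pos + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        position = pos, surface = surface, flags = flags,
        phrase_id = phrase, stringsAsFactors = FALSE)
    }
    order_items <- if (length(produced_items) > 1)
      sample(produced_items) else produced_items
    for (id in order_items) {
      row <- items[items$item_id == id, ]
      if (stats::runif(1) < config$filler_rate)
        emit(sample(.filler_pool, 1), "filler")
      u <- stats::runif(1)
      syns <- checklist$synonyms[[id]]
      surf <- if (u < 0.35) inflect_surface(row$lemma, row$word_class)
      else if (u < 0.55 && length(syns)) sample(rep(syns, 2), 1)
      else row$lemma
      emit(surf)
      if (stats::runif(1) < config$repetition_rate) emit(surf)
      n_ctx <- stats::rpois(1, 1.2)
      if (n_ctx > 0) for (w in sample(rep(.context_pool, 2), n_ctx)) {
        r <- stats::runif(1)
        if (r < 0.03) emit(sample(.offtopic_pool, 1), "off_topic")
        else if (r < 0.05) emit("xxx", "unintelligible")
        else if (r < 0.07) emit(sample(.nonword_pool, 1), "non_word")
        else emit(w)
      }
      in_phrase <- in_phrase + 1L
      if (in_phrase >= sample(2:4, 1)) { phrase <- phrase + 1L; in_phrase <- 0L }
    }
    if (!length(rows)) emit(sample(.filler_pool, 1), "filler")
    transcript(pid, do.call(rbind, rows))
  })
}

#' Generate a synthetic cohort
#'
#' Runs the full generative model: checklist with standard-normal
#' difficulties `b`; connected lesion blobs with log-normal target sizes;
#' per-person latent ability `theta = -effect_beta * load + noise`, where
#' `load` is the lesioned fraction of the critical region and noise is
#' `N(0, noise_sd)`; item production `Bernoulli(plogis(theta - b))`; and
#' transcripts embedding the produced items among fillers, inflections,
#' synonyms, adjacent repetitions and extra stimulus-relevant context words
#' (so `CWF <= CIU <= word count` on every transcript). The behaviour
#' table (CWF, CIU, word count, severity on an AQ-like 0-100 scale,
#' aphasia subtype by ability rank, lesion size) is pre-computed.
#'
#' Randomness is partitioned into per-stage child seeds of `config$seed`,
#' so changing `effect_beta` alone reuses identical lesion, noise and
#' production draws -- which makes mean CWF deterministically
#' non-increasing in `effect_beta`.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_cohort`: `checklist`, `transcripts`,
#'   `lesions`, `abilities`, `tract_atlas`, `streamlines`,
#'   `true_difficulties`, `behavior`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_participants
  grid <- config$grid_shape
  cl <- generate_checklist(config$n_items, config$seed)
  b <- attr(cl, "true_difficulties")
  atlas <- generate_tract_atlas(grid)
  pids <- sprintf("sub%03d", seq_len(n))

  targets <- with_seed(child_seed(config$seed, 2), {
    round(stats::rlnorm(n, meanlog = log(0.015 * prod(grid)), sdlog = 0.7))
  })
  territory <- if (length(config$critical_region))
    colMeans(arrayInd(config$critical_region, grid)) else grid / 2
  vols <- lapply(seq_len(n), function(i) {
    lesion_volume(grow_lesion_blob(grid, targets[i],
                                   child_seed(config$seed, 200 + i),
                                   territory_center = territory),
                  voxel_size_mm = config$voxel_size_mm)
  })
  lesions <- cohort_lesions(pids, vols)
  loads <- vapply(vols, function(v) {
    if (length(config$critical_region))
      mean(v$data[config$critical_region]) else 0
  }, numeric(1))
  eps <- with_seed(child_seed(config$seed, 3),
                   stats::rnorm(n, 0, config$noise_sd))
  theta <- -config$effect_beta * loads + eps
  U <- with_seed(child_seed(config$seed, 4),
                 matrix(stats::runif(n * config$n_items), nrow = n))
  produced <- if (n)
    U < t(irf_matrix(theta, rep(1, config$n_items), b, rep(0, config$n_items)))
  else matrix(FALSE, 0, config$n_items)
  colnames(produced) <- cl$items$item_id

  transcripts <- lapply(seq_len(n), function(i) {
    assemble_transcript(pids[i], cl$items$item_id[produced[i, ]], cl, config,
                        child_seed(config$seed, 40000 + i))
  })
  streamlines <- generate_streamlines(atlas, n_per_tract = 12,
                                      seed = child_seed(config$seed, 5))

  scores <- lapply(transcripts, score_cwf, checklist = cl)
  behavior <- data.frame(
    participant_id = pids,
    CWF = vapply(scores, `[[`, integer(1), "total"),
    CIU = vapply(transcripts, count_cius, integer(1)),
    word_count = vapply(transcripts, word_count, integer(1)),
    severity = round(pmin(100, pmax(0, 75 + 12 * theta)), 1),
    lesion_size_cc = lesions$lesion_size_cc,
    stringsAsFactors = FALSE)
  behavior$aphasia_type <- assign_subtypes(theta)
  structure(list(checklist = cl, transcripts = transcripts, lesions = lesions,
                 abilities = theta, tract_atlas = atlas,
                 streamlines = streamlines,
                 true_difficulties = b, behavior = behavior,
                 cwf_results = scores, config = config),
            class = "synthetic_cohort")
}

# subtype labels by ability rank, in the class proportions of typical
# chronic left-hemisphere stroke cohorts (non-fluent types at low ability)
assign_subtypes <- function(theta) {
  n <- length(theta)
  if (!n) return(character(0))
  props <- c(broca = 17, wernicke = 2, conduction = 10,
             transcortical_motor = 3, transcortical_sensory = 2, anomic = 41)
  counts <- round(props / sum(props) * n)
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  counts["anomic"] <- counts["anomic"] + (n - sum(counts))
  labels <- rep(names(counts), counts)
  labels[order(order(theta))]   # lowest ability -> broca, highest -> anomic
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d-item checklist, grid %s\n",
              x$config$n_participants, x$config$n_items,
              paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}

#' Generate a streamline template within a tract atlas
#'
#' For each tract, draws `n_per_tract` voxel paths: two random tract voxels
#' joined by a breadth-first shortest path constrained to the tract dilated
#' by one 6-neighbour step, so every path voxel lies within the dilated
#' tract and every tract contributes at least one streamline.
#'
#' @param tract_atlas a [tract_atlas()] with non-empty tracts.
#' @param n_per_tract streamlines per tract (>= 1).
#' @param seed integer seed.
#' @return a [streamline_set()].
#' @export
generate_streamlines <- function(tract_atlas, n_per_tract = 10, seed = 1) {
  stopifnot(inherits(tract_atlas, "tract_atlas"))
  n_per_tract <- assert_count(n_per_tract, "n_per_tract", min = 1L)
  grid <- tract_atlas$grid
  paths <- list()
  with_seed(child_seed(seed, 7), {
    for (nm in names(tract_atlas$tracts)) {
      vox <- tract_atlas$tracts[[nm]]
      dil <- dilate_voxels(vox, grid)
      for (s in seq_len(n_per_tract)) {
        ends <- if (length(vox) >= 2) sample(vox, 2) else c(vox, vox)
        path <- bfs_path(ends[1], ends[2], dil, grid)
        paths[[length(paths) + 1L]] <- path
      }
    }
  })
  streamline_set(paths, grid)
}

dilate_voxels <- function(vox, grid) {
  arr <- array(FALSE, dim = grid)
  arr[vox] <- TRUE
  co <- arrayInd(vox, grid)
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  out <- logical(prod(grid))
  for (o in seq_len(nrow(offs))) {
    sh <- sweep(co, 2, offs[o, ], `+`)
    ok <- sh[, 1] >= 1 & sh[, 1] <= grid[1] & sh[, 2] >= 1 &
      sh[, 2] <= grid[2] & sh[, 3] >= 1 & sh[, 3] <= grid[3]
    sh <- sh[ok, , drop = FALSE]
    out[(sh[, 3] - 1) * grid[1] * grid[2] + (sh[, 2] - 1) * grid[1] + sh[, 1]] <- TRUE
  }
  which(out)
}

bfs_path <- function(from, to, allowed, grid) {
  if (from == to) return(from)
  allow <- logical(prod(grid)); allow[allowed] <- TRUE
  prev <- integer(prod(grid))
  queue <- from; visited <- logical(prod(grid)); visited[from] <- TRUE
  nxy <- grid[1] * grid[2]
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == to) break
    co <- arrayInd(cur, grid)
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      nb <- co + d
      if (any(nb < 1) || any(nb > grid)) next
      lin <- (nb[3] - 1) * nxy + (nb[2] - 1) * grid[1] + nb[1]
      if (!allow[lin] || visited[lin]) next
      visited[lin] <- TRUE; prev[lin] <- cur
      queue <- c(queue, lin)
    }
  }
  if (!visited[to]) return(c(from, to))  # disconnected tract: degenerate path
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

#' Write a synthetic cohort to disk
#'
#' Emits token-per-line transcript TSVs, per-subject NIfTI lesion masks,
#' a behaviour TSV, checklist JSON, tract-atlas and streamline JSON, and a
#' manifest JSON listing every output with the generating seed and package
#' version.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tdir <- file.path(dir, "transcripts"); dir.create(tdir, showWarnings = FALSE)
  ldir <- file.path(dir, "lesions"); dir.create(ldir, showWarnings = FALSE)
  files <- character()
  for (tr in cohort$transcripts) {
    f <- file.path(tdir, paste0(tr$participant_id, ".tsv"))
    write_transcript_tsv(tr, f); files <- c(files, f)
  }
  for (i in seq_along(cohort$lesions$subjects)) {
    f <- file.path(ldir, paste0(cohort$lesions$subjects[i], ".nii.gz"))
    write_lesion_nifti(cohort$lesions$volumes[[i]], f); files <- c(files, f)
  }
  bf <- file.path(dir, "behaviour.tsv")
  utils::write.table(cohort$behavior, bf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cf <- file.path(dir, "checklist.json"); write_checklist(cohort$checklist, cf)
  af <- file.path(dir, "tract_atlas.json")
  write_tract_atlas_json(cohort$tract_atlas, af)
  sf <- file.path(dir, "streamlines.json")
  write_streamlines_json(cohort$streamlines, sf)
  files <- c(files, bf, cf, af, sf)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    seed = cohort$config$seed,
    package_version = as.character(utils::packageVersion("discoursemap")),
    n_participants = cohort$config$n_participants,
    files = basename(files)), mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mf)
}
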