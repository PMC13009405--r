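test_that("generated checklists span the documented covariate ranges", {
  cl <- generate_checklist(22, seed = 1)
  expect_equal(nrow(cl$items), 22L)
  expect_false(anyDuplicated(cl$items$item_id) > 0)
  expect_true(all(cl$items$length_phonemes >= 2 & cl$items$length_phonemes <= 7))
  expect_true(all(cl$items$frequency >= 0.77 & cl$items$frequency <= 4.56))
  expect_true(all(cl$items$imageability >= 230 & cl$items$imageability <= 638))
  expect_true(all(lengths(cl$synonyms) <= 3))
  b <- attr(cl, "true_difficulties")
  expect_length(b, 22L)
  expect_true(all(is.finite(b)))
  # single item is valid; zero items is not
  expect_equal(nrow(generate_checklist(1, seed = 2)$items), 1L)
  expect_error(generate_checklist(0), "n_items")
  # identical seed, identical checklist
  expect_identical(generate_checklist(22, seed = 3), generate_checklist(22, seed = 3))
  # more items than the vocabulary pool still yields unique lemmas
  big <- generate_checklist(40, seed = 4)
  expect_false(anyDuplicated(big$items$lemma) > 0)
})

test_that("configuration validation catches bad inputs", {
  expect_error(simulation_config(filler_rate = 1.5), "probability")
  expect_error(simulation_config(grid_shape = c(8, 8)), "grid_shape")
  expect_error(simulation_config(critical_region = integer(), effect_beta = 1),
               "empty critical_region")
  cfg0 <- simulation_config(critical_region = integer(), effect_beta = 0,
                            n_participants = 0)
  expect_equal(length(cfg0$critical_region), 0L)
  expect_error(simulation_config(critical_region = 1e9), "outside the grid")
})

test_that("an empty cohort is generated without error", {
  cfg <- simulation_config(n_participants = 0, grid_shape = c(8, 8, 8), seed = 2)
  coh <- generate_cohort(cfg)
  expect_length(coh$transcripts, 0L)
  expect_equal(nrow(coh$behavior), 0L)
  expect_length(coh$abilities, 0L)
})

test_that("cohorts are byte-identical under the same configuration", {
  cfg <- simulation_config(n_participants = 12, grid_shape = c(10, 10, 10),
                           seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$abilities, b$abilities)
  expect_identical(lapply(a$transcripts, `[[`, "tokens"),
                   lapply(b$transcripts, `[[`, "tokens"))
  expect_identical(lapply(a$lesions$volumes, `[[`, "data"),
                   lapply(b$lesions$volumes, `[[`, "data"))
})

test_that("critical-region load depresses scores when noise vanishes", {
  cfg <- simulation_config(n_participants = 50, grid_shape = c(16, 16, 16),
                           noise_sd = 0, effect_beta = 3, seed = 9)
  coh <- generate_cohort(cfg)
  loads <- vapply(coh$lesions$volumes,
                  function(v) mean(v$data[cfg$critical_region]), numeric(1))
  expect_gt(sd(loads), 0)
  expect_lt(cor(loads, coh$behavior$CWF), 0)
})

test_that("mean CWF is non-increasing in the lesion effect size", {
  base <- list(n_participants = 40, grid_shape = c(16, 16, 16), seed = 3,
               noise_sd = 0.8)
  means <- vapply(c(0, 1.5, 3), function(beta) {
    cfg <- do.call(simulation_config, c(base, list(effect_beta = beta)))
    mean(generate_cohort(cfg)$behavior$CWF)
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("scoring bounds hold on every generated transcript", {
  for (s in 1:3) {
    cfg <- simulation_config(n_participants = 40, grid_shape = c(10, 10, 10),
                             seed = s)
    coh <- generate_cohort(cfg)
    cwf <- coh$behavior$CWF
    ciu <- coh$behavior$CIU
    wc <- coh$behavior$word_count
    expect_true(all(cwf <= ciu))
    expect_true(all(ciu <= wc))
  }
})

test_that("streamlines stay within dilated tracts and count correctly", {
  atlas <- tract_atlas(list(a = discoursemap::default_critical_region(c(12, 12, 12)),
                            b = 1:6), c(12L, 12L, 12L))
  sl <- generate_streamlines(atlas, n_per_tract = 5, seed = 1)
  expect_length(sl$streamlines, 10L)
  for (nm in names(atlas$tracts)) {
    dil <- discoursemap:::dilate_voxels(atlas$tracts[[nm]], c(12L, 12L, 12L))
    idx <- if (nm == "a") 1:5 else 6:10
    for (p in sl$streamlines[idx]) expect_true(all(p %in% dil))
  }
  expect_identical(generate_streamlines(atlas, 5, seed = 1), sl)
  expect_error(generate_streamlines(atlas, 0), "n_per_tract")
})

test_that("lesion blobs are connected and near the requested size", {
  mask <- discoursemap:::grow_lesion_blob(c(14L, 14L, 14L), 120L, seed = 5)
  expect_equal(sum(mask), 120L)
  # connectivity: breadth-first flood from one voxel reaches all
  vox <- which(mask)
  grid <- dim(mask)
  seen <- logical(prod(grid)); seen[vox[1]] <- TRUE
  queue <- vox[1]
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    co <- arrayInd(cur, grid)
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      nb <- co + d
      if (any(nb < 1) || any(nb > grid)) next
      lin <- (nb[3] - 1) * grid[1] * grid[2] + (nb[2] - 1) * grid[1] + nb[1]
      if (mask[lin] && !seen[lin]) { seen[lin] <- TRUE; queue <- c(queue, lin) }
    }
  }
  expect_true(all(seen[vox]))
})

test_that("write_cohort emits a complete, re-readable file set", {
  cfg <- simulation_config(n_participants = 4, grid_shape = c(8, 8, 8), seed = 11)
  coh <- generate_cohort(cfg)
  dir <- tempfile()
  manifest <- write_cohort(coh, dir)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_equal(man$n_participants, 4L)
  expect_true(all(c("behaviour.tsv", "checklist.json", "streamlines.json",
                    "tract_atlas.json") %in% man$files))
  tback <- read_transcript_tsv(file.path(dir, "transcripts", "sub001.tsv"))
  expect_equal(tback$tokens$surface, coh$transcripts[[1]]$tokens$surface)
  lback <- read_lesion_nifti(file.path(dir, "lesions", "sub001.nii.gz"))
  expect_equal(lback$data, coh$lesions$volumes[[1]]$data)
  beh <- utils::read.delim(file.path(dir, "behaviour.tsv"))
  expect_equal(beh$CWF, coh$behavior$CWF)
})
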