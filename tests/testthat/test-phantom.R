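# Phantom generators: piecewise-smooth line phantoms and the procedural
# labelled brain volume with letter inscription.

test_that("a single unsoftened plateau yields four constant vectors", {
  ph <- line_phantom(line_phantom_config(n = 20, segments = c(1, 1),
                                         smooth_width = 0, seed = 5))
  for (p in c("S0", "D", "V", "T1")) {
    expect_equal(length(unique(ph[[p]])), 1L)
  }
})

test_that("line phantoms stay strictly inside the fit bounds for any seed", {
  b <- default_fit_bounds()
  for (seed in 1:20) {
    ph <- line_phantom(line_phantom_config(n = 50, seed = seed))
    for (p in names(b)) {
      expect_true(all(ph[[p]] > b[[p]][1] & ph[[p]] < b[[p]][2]))
    }
  }
})

test_that("an ensemble of phantoms spans most of each configured range", {
  cfg <- line_phantom_config(n = 50, seed = 1)
  ensemble <- lapply(1:50, function(s) {
    cfg$seed <- s
    line_phantom(cfg)
  })
  for (p in c("S0", "D", "V", "T1")) {
    vals <- unlist(lapply(ensemble, `[[`, p))
    covered <- diff(range(vals)) / diff(cfg$ranges[[p]])
    expect_gte(covered, 0.8)
  }
})

test_that("multi-plateau phantoms keep exact step edges when unsmoothed", {
  ph <- line_phantom(line_phantom_config(n = 40, segments = c(3, 3),
                                         smooth_width = 0, seed = 2))
  steps <- which(diff(ph$D) != 0)
  expect_gte(length(steps), 1L)
  # plateau values on both sides of a step are exactly constant
  e <- steps[1]
  expect_equal(ph$D[e], ph$D[max(1, e - 1)])
})

test_that("phantom generation is deterministic per seed", {
  cfg <- line_phantom_config(n = 30, seed = 77)
  expect_identical(line_phantom(cfg), line_phantom(cfg))
})

test_that("brain phantom labels partition the volume and parameters follow the table", {
  vol <- brain_phantom(shape = c(16, 16, 14), seed = 3)
  expect_true(all(vol$labels %in% c(0L, vol$tissue_params$label)))
  expect_true(all((vol$maps$S0 > 0) == (vol$labels != 0L)))
  for (i in seq_len(nrow(vol$tissue_params))) {
    sel <- vol$labels == vol$tissue_params$label[i]
    expect_true(any(sel))  # every tissue shell is realized
    expect_equal(unique(vol$maps$D[sel]), vol$tissue_params$D[i])
  }
  # identical per-tissue values give spatially constant maps on the support
  tp <- default_tissue_params()
  tp$S0 <- 2; tp$D <- 1; tp$V <- 0.5; tp$T1 <- 1.1
  flat <- brain_phantom(shape = c(12, 12, 10), tissue_params = tp, seed = 3)
  expect_equal(unique(flat$maps$T1[flat$labels != 0L]), 1.1)
})

test_that("brain phantom is voxel-identical across reruns with one seed", {
  a <- brain_phantom(shape = c(14, 14, 12), seed = 9)
  b <- brain_phantom(shape = c(14, 14, 12), seed = 9)
  expect_identical(a$maps, b$maps)
  expect_identical(a$labels, b$labels)
})

test_that("letter inscription perturbs maps inside disjoint masks only", {
  vol <- brain_phantom(shape = c(40, 16, 30), seed = 1)
  expect_identical(inscribe_letters(vol, "", list(), integer()), vol)
  ins <- inscribe_letters(vol, "LU",
                          locations = list(c(4L, 7L, 4L), c(14L, 7L, 14L)),
                          sizes = c(1L, 2L))
  expect_length(ins$letter_masks, 2L)
  expect_false(any(ins$letter_masks[[1]] & ins$letter_masks[[2]]))
  changed <- ins$maps$D != vol$maps$D
  expect_true(all(changed[!(ins$letter_masks[[1]] | ins$letter_masks[[2]])] == FALSE))
  # legibility contrast is positive right after inscription
  ctr <- letter_contrast(ins$maps, ins$letter_masks, ins$labels != 0L)
  expect_gt(ctr$contrast[ctr$parameter == "D"], 0)
  expect_gt(ctr$contrast[ctr$parameter == "T1"], 0)
})

test_that("letter masks outside the volume are rejected", {
  vol <- brain_phantom(shape = c(12, 12, 10), seed = 2)
  expect_error(inscribe_letters(vol, "LU", list(c(8L, 4L, 2L)), 2L),
               "exceeds volume bounds")
})
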