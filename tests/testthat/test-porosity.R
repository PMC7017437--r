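test_that("binarize follows the dark-bone convention and handles edge cases", {
  g <- matrix(0, 5, 5)
  expect_true(all(suppressWarnings(binarize(g, 0.5))$bone))
  chk <- matrix(c(0, 1), 4, 4)                 # alternating columns of 0/1
  s <- binarize(chk, 0.5)
  expect_identical(sum(s$bone), 8L)
  expect_warning(binarize(matrix(0.3, 3, 3), 0.3), "constant")
})

test_that("crest apices: plateaus give midpoints, prominence filters noise", {
  # full-width flat-topped rectangle: one border-to-border plateau,
  # prominence zero -> kept only when the filter allows it
  bone <- matrix(TRUE, 6, 11)
  s <- binary_section(bone)
  expect_identical(nrow(detect_crest_apices(s, "top")), 0L)
  ap0 <- detect_crest_apices(s, "top", min_prominence = 0)
  expect_identical(ap0$col, 6L)                # midpoint of 1..11
  # the same rectangle inset in void: flanked by no-bone columns, the
  # plateau is maximally prominent
  bone2 <- matrix(FALSE, 8, 15)
  bone2[3:6, 4:10] <- TRUE
  ap <- detect_crest_apices(binary_section(bone2), "top")
  expect_identical(ap$col, 7L)                 # midpoint of 4..10
  expect_identical(ap$row, 3L)
  expect_error(detect_crest_apices(binary_section(matrix(FALSE, 3, 3))),
               "no bone")
})

test_that("the 7x15 two-crest toy raster yields two apices", {
  s <- binary_section(two_crest_raster())
  ap <- detect_crest_apices(s, "top")
  expect_identical(nrow(ap), 2L)
  expect_identical(ap$col, c(4L, 12L))
  expect_identical(ap$row, c(3L, 3L))
})

test_that("bridging equal-height crests draws the horizontal chord and encloses the pit", {
  s <- binary_section(two_crest_raster())
  ap <- detect_crest_apices(s, "top")
  b <- bridge_crests(s, ap, "top")
  expect_true(attr(b, "bridged"))
  # chord on the apex row: void columns 6..10 at row 3 become bone
  expect_identical(attr(b, "bridge_length"), 5L)
  expect_true(all(b$bone[3, 4:12]))
  # pit now enclosed: rows 3..4 were open before, enclosed after
  before <- measure_vascular_area(s)
  after <- measure_vascular_area(s, bridge = TRUE, side = "top")
  expect_identical(before$vascular_area, 0L)
  # enclosed pit = the 5 void pixels of row 4 under the chord
  expect_identical(after$vascular_area, 5L)
  # bridging never decreases porosity
  expect_gte(after$porosity, before$porosity)
})

test_that("bridging is idempotent and a no-op below two apices", {
  s <- binary_section(two_crest_raster())
  once <- measure_vascular_area(s, bridge = TRUE, side = "top")
  ap1 <- detect_crest_apices(s, "top")
  b1 <- bridge_crests(s, ap1, "top")
  twice <- measure_vascular_area(b1, bridge = TRUE, side = "top")
  expect_identical(twice$porosity, once$porosity)
  flat <- binary_section(matrix(TRUE, 4, 9))
  unbridged <- bridge_crests(flat, detect_crest_apices(flat, "top"), "top")
  expect_false(attr(unbridged, "bridged"))
  expect_identical(unbridged$bone, flat$bone)
})

test_that("porosity of constructed sections: solid -> 0, half-void annulus -> 0.5", {
  solid <- matrix(FALSE, 24, 24); solid[3:22, 3:22] <- TRUE
  expect_identical(measure_vascular_area(binary_section(solid))$porosity, 0)
  annulus <- matrix(FALSE, 22, 20)
  annulus[3:20, 3:18] <- TRUE                  # 18 x 16 block = 288 px
  annulus[5:16, 5:16] <- FALSE                 # 12 x 12 enclosed void = 144 px
  r <- measure_vascular_area(binary_section(annulus))
  expect_identical(r$vascular_area, 144L)
  expect_identical(r$total_area, 288L)
  expect_identical(r$porosity, 0.5)
  expect_error(measure_vascular_area(binary_section(matrix(FALSE, 2, 2))),
               "zero total area|no bone")
})

test_that("porosity equals the flood-fill oracle and is rotation/flip invariant", {
  set.seed(42)
  for (rep in 1:8) {
    gen <- generate_section(90, 70, target_porosity = runif(1, 0.05, 0.3),
                            seed = 100 + rep)
    bone <- gen$section$bone
    r <- measure_vascular_area(gen$section)
    expect_identical(r$vascular_area, flood_fill_enclosed(bone))
    # 90-degree rotation and mirror flips leave the fraction unchanged
    rot <- binary_section(t(bone)[ncol(bone):1, , drop = FALSE])
    flip <- binary_section(bone[nrow(bone):1, , drop = FALSE])
    expect_equal(measure_vascular_area(rot)$porosity, r$porosity)
    expect_equal(measure_vascular_area(flip)$porosity, r$porosity)
  }
})

test_that("on unornamented sections bridging changes nothing", {
  gen <- generate_section(120, 90, target_porosity = 0.2, seed = 7)
  plain <- measure_vascular_area(gen$section)
  bridged <- measure_vascular_area(gen$section, bridge = TRUE, side = "top")
  expect_identical(bridged$porosity, plain$porosity)
})

test_that("section images round-trip through PNG and TIFF", {
  gen <- generate_section(60, 50, target_porosity = 0.15, seed = 3)
  for (ext in c(".png", ".tiff")) {
    f <- withr::local_tempfile(fileext = ext)
    write_section(gen$section, f)
    back <- read_section(f)
    expect_identical(back$bone, gen$section$bone)
  }
})

test_that("synthetic grayscale sections binarize back to their mask", {
  gen <- generate_section(80, 60, target_porosity = 0.2, seed = 11)
  gray <- ifelse(gen$section$bone, 0.1, 0.9)   # dark bone, light void
  gray <- matrix(gray, nrow(gen$section$bone))
  expect_identical(binarize(gray, 0.5)$bone, gen$section$bone)
})
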