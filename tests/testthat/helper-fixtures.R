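# Shared fixtures, built once per test run and cached for the session.
#
# The "standard fixture" is the stated world of the end-to-end checks:
# a 2-level toy model trained on 200 seeded 48x48 phantoms (the package
# defaults), evaluated on a held-out set of 60 phantoms, with TP-based
# P95 calibration. The block-sensitivity fixture is a 5-level model on
# 64x64 phantoms so the sweep exposes the full 10-block registry.

.fixtureCache <- new.env(parent = emptyenv())

fixtureCached <- function(key, build) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- build()
  .fixtureCache[[key]]
}

fixturePhantoms <- function() {
  fixtureCached("phantoms", function() {
    generatePhantoms(phantomSpec(nImages = 200L, seed = 101L))
  })
}

fixtureTestSet <- function() {
  fixtureCached("testset", function() {
    generatePhantoms(phantomSpec(nImages = 60L, seed = 555L))
  })
}

fixtureModel <- function() {
  fixtureCached("model", function() {
    model <- buildToyModel(toyModelSpec(levels = 2L, channels = 4L,
                                        classes = 2L, seed = 1L))
    trainToyModel(model, fixturePhantoms(), epochs = 8L, seed = 2L)
  })
}

# Scored regions of the whole held-out set, with TP/FP flags and TP-based
# calibration references for all three measures.
fixtureScores <- function() {
  fixtureCached("scores", function() {
    model <- fixtureModel()
    ts <- fixtureTestSet()
    recs <- list()
    for (i in seq_along(ts$images)) {
      lm <- predictLabelMap(model, ts$images[[i]])
      rs <- extractRegions(lm, minVolumeCm3 = 0.25)
      if (nRegions(rs) == 0L) next
      tb <- scoreRegions(model, ts$images[[i]], rs)
      tb$is_tp <- classifyDetections(rs, ts$truth[[i]])$is_tp
      tb$image <- i
      recs[[length(recs) + 1L]] <- tb
    }
    records <- do.call(rbind, recs)
    refs <- list(
      lg = calibrateReference(records$lg[records$is_tp], "lg", source = "TP regions"),
      mp = calibrateReference(records$mp[records$is_tp], "mp", source = "TP regions"),
      kld = calibrateReference(records$kld[records$is_tp], "kld", source = "TP regions")
    )
    list(records = applyCalibration(records, refs), refs = refs)
  })
}

# 5-level model for the block-configuration sweep (needs 64x64 inputs).
# Distractor sizes overlap the lesion range so FPs arise reliably.
fixtureSweep <- function() {
  fixtureCached("sweep", function() {
    ph <- generatePhantoms(phantomSpec(nImages = 32L, dim = c(64L, 64L),
                                       distractorRate = 0.9,
                                       distractorRadius = c(2.6, 4.2),
                                       seed = 77L))
    model <- buildToyModel(toyModelSpec(levels = 5L, channels = 4L,
                                        classes = 2L, seed = 3L))
    model <- trainToyModel(model, ph, epochs = 10L, lr = 2e-3, seed = 4L)
    list(model = model, phantoms = ph)
  })
}

# A small model and image for gradient-level checks (1172 parameters).
tinyModelImage <- function(seed = 5L, imageSeed = 42L) {
  model <- buildToyModel(toyModelSpec(levels = 2L, channels = 2L,
                                      classes = 2L, seed = seed))
  img <- ScanImage(matrix(withSeed2(imageSeed, stats::rnorm(16 * 16)), 16, 16),
                   c(4, 4))
  list(model = model, image = img)
}

# local seeded RNG for test inputs
withSeed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(expr)
}

rscriptBin <- function() file.path(R.home("bin"), "Rscript")

cliScript <- function() {
  path <- system.file("cli", "graduq.R", package = "gradUQ")
  stopifnot(nzchar(path))
  path
}

runCli <- function(args) {
  res <- suppressWarnings(system2(rscriptBin(), c(cliScript(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  list(status = if (is.null(status)) 0L else status, output = res)
}
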