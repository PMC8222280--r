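# Shared fixtures. Unit and property tests run on a scaled-down phantom
# (48 x 48 x 32 at 3 mm, ~20 cc dose bins) so the whole suite stays fast;
# the acceptance tests use the full default presets.

tinyConfig <- function(preset = "swine", seed = 1L, ...) {
  phantomConfig(
    preset, seed = seed,
    gridShape = c(48L, 48L, 32L),
    spacing = c(3, 3, 3),
    lung = list(semiAxesMm = c(28, 48, 38), sepMm = 74,
                centerYMm = 69, centerZMm = 45),
    vessels = list(nBranches = 40L, radiusRangeMm = c(1.5, 3.0),
                   hilumOffsetMm = 16),
    dose = list(targetBinCc = 20, minCc = 15),
    ...)
}

.fixtures <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

tinySwine <- function(seed = 1L) {
  cachedFixture(paste0("tinySwine", seed),
                simulateSwineSubject(seed, tinyConfig("swine", seed = seed)))
}

tinyHuman <- function(seed = 1L, timepoint = "12") {
  cachedFixture(paste0("tinyHuman", seed, "_", timepoint),
                simulateHumanSubject(seed, timepoint,
                                     tinyConfig("human", seed = seed)))
}

# small random grid for I/O and geometry tests
randomGrid <- function(dim = c(8, 8, 8), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), seed = 42) {
  set.seed(seed)
  ImageGrid(array(rnorm(prod(dim)), dim), spacing = spacing,
            origin = origin)
}

# constant-frame series builder for trace/MIP tests
constantSeries <- function(frameValues, spacing = c(1, 1, 1),
                           nPrecontrast = 1L) {
  frames <- lapply(frameValues, function(v) {
    ImageGrid(if (is.array(v)) v else array(v, c(4, 4, 4)),
              spacing = spacing)
  })
  DynamicSeries(frames, times = seq_along(frames),
                nPrecontrast = nPrecontrast)
}
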