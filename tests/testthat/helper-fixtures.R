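# Shared small fixtures built in code at test time.

# A small, fast phantom geometry (12^3 grid, spherical core).
tinySpec <- function(supersample = 2L) {
  phantomSpec(gridShape = c(12, 12, 12), voxelSize = c(1, 1, 1),
              wmSemiaxes = c(3, 3, 3), gmThickness = 2, csfThickness = 1,
              supersample = supersample)
}

# The default study geometry (40^3, WM radius 12 mm).
studySpec <- function(supersample = 3L)
  phantomSpec(supersample = supersample)

# Random BoundaryDensityMap for normative-model tests.
randomDensity <- function(d = c(6, 6, 6), kernel = 5L, seed = 1) {
  set.seed(seed)
  boxConvolve(array(rbinom(prod(d), 1, 0.3), d), kernel)
}
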