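# Shared fixtures. Eigenmode bases are cached inside the package, so
# repeated calls across test files are cheap.

icoMesh <- function(n) buildIcosphere(n)

# random unit vectors, deterministic
randomSpherePoints <- function(n, seed = 1) {
  set.seed(seed)
  p <- matrix(rnorm(3 * n), n)
  p / sqrt(rowSums(p^2))
}

smoothMap <- function(mesh, seed = 1, gamma = 3, nModes = 150,
                      noiseSd = 0.1) {
  basis <- meshEigenmodes(mesh, nModes + 1)
  synthMap(mesh, synthSpec(gamma = gamma, nModes = nModes,
                           noiseSd = noiseSd, seed = seed), basis = basis)
}

whiteNoiseMap <- function(mesh, seed = 1)
  synthMap(mesh, synthSpec(gamma = 0, nModes = 0, noiseSd = 1, seed = seed))

# small-lattice config used by most pipeline tests (fast, fixed lambda)
smallConfig <- function(...)
  latticeConfig(utils::modifyList(list(baseSubdivision = 1, lambda = 0.01),
                                  list(...)))

# single-level test lattice on the sphere
oneLevelLattice <- function(subdivision = 1, rangeMultiplier = 2.5)
  buildSphereLattice(1, subdivision, rangeMultiplier, alpha = 1)
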