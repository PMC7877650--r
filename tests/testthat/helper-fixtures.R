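# Shared fixtures, built in code at test time.

unit_square <- function() {
  validity_domain(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
}

square_with_hole <- function() {
  validity_domain(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                  holes = list(cbind(c(0.35, 0.65, 0.65, 0.35),
                                     c(0.35, 0.35, 0.65, 0.65))))
}

# three tight blobs at asymmetric centers: each blob sees the others at a
# distinct set of distances, so growth curves sampled at radii away from
# those distances separate the blobs into three near-atomic feature groups
asym_blobs <- function(n = 1500, sd = 0.01, seed = 5) {
  centers <- rbind(c(0.2, 0.2), c(0.5, 0.25), c(0.85, 0.8))
  generate_fixture(synthetic_spec("blobs", n,
                                  params = list(centers = centers, sd = sd),
                                  seed = seed))
}

step_radii <- function() c(0.15, 0.45, 0.75, 0.99)

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
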