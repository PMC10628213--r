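## shared fixtures: random valid stacks and a quick noiseless curve

randomStack <- function(nmax = 6L, fronting = mediumAir(),
                        backing = mediumSilicon()) {
  n <- sample.int(nmax, 1L)
  slabs <- replicate(n, Slab(runif(1, 3, 60), runif(1, 0, 0.8),
                             runif(1, 0, 8)), simplify = FALSE)
  suppressWarnings(LayerStack(fronting, slabs, backing,
                              backingRoughness = runif(1, 0, 8)))
}

bareInterface <- function(fronting = mediumAir(), backing = mediumSilicon(),
                          sigma = 0) {
  LayerStack(fronting, list(), backing, backingRoughness = sigma)
}

## closed-form Fresnel reflectivity of a sharp interface for q > qc
fresnelSharp <- function(q, qc) {
  s <- sqrt(1 - (qc / q)^2)
  ((1 - s) / (1 + s))^2
}
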