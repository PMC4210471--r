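# shared test utilities: canonical pair keys and quick random instances

pairKey <- function(vm) {
  p <- joinPairs(vm)
  sort(paste(p$variant, p$region, sep = ":"))
}

# a mid-sized genome where kilobase windows still hit things
testGenome <- function() genomeModel(c("chrA", "chrB"), c(100000, 50000))

randomInstance <- function(seed, nVariants = 200, nRegions = 100,
                           gm = testGenome(), lengthLaw = c(5, 100)) {
  list(variants = simulateVariants(nVariants, gm, seed),
       regions = simulateFeature(nRegions, lengthLaw, c(0, 1), gm,
                                 seed + 1000003))
}

tmpStore <- function(regions, name = "feat", type = "numeric") {
  buildFeatureStore(regions, name, type, tempfile(fileext = ".vasf"))
}
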