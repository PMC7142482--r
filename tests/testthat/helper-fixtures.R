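# Shared fixture builders; everything is generated in code at test time.

smallGrid <- function(n = 2048L) defaultGrid(n)

smallDefs <- function(n = 5L) defaultMetabolites(n)

smallLibrary <- function(n = 5L, grid = smallGrid()) {
  makeSpectralLibrary(smallDefs(n), grid)
}

# a cohort design over the four cell lines (cell extracts)
fourLineDesign <- function(effects = list(), seed = 42L, cv = 0,
                           noiseSd = 0, replicates = 3L,
                           nMetabolites = 5L) {
  nm <- names(defaultMetabolites(nMetabolites))
  cohortDesign(
    groups = data.frame(cellLine = c("LN18", "A172", "U118", "NHA"),
                        sourceType = "cell"),
    replicatesPerGroup = replicates,
    baseConcentrations = setNames(rep(1, length(nm)), nm),
    effects = effects, biologicalCV = cv, noiseSd = noiseSd, seed = seed)
}

allToyKinds <- c("chain", "branched", "mini_tca", "glutathione")
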