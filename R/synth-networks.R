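#' Toy stoichiometric networks
#'
#' Small, fully specified models for exercising and verifying the flux
#' machinery: a linear chain, a branched network with two gene-gated
#' alternative routes, a TCA-cycle fragment (citrate to malate, with the
#' succinate -> fumarate -> malate direction explicit), and a
#' glutathione-like branch (reduced/oxidized glutathione interconversion
#' plus a 5-oxoproline branch). Every model has exactly one objective
#' (biomass/maintenance) reaction and a consistent stoichiometric matrix,
#' and each fits in at most eight reactions so brute-force LP oracles remain
#' tractable.
#'
#' @name toy-networks
NULL

toyModel <- function(mets, rxns, objective, genes = character(0)) {
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, names(rxns)))
  lb <- ub <- numeric(length(rxns))
  gpr <- character(length(rxns))
  for (j in seq_along(rxns)) {
    r <- rxns[[j]]
    for (m in names(r$mets)) S[m, j] <- r$mets[[m]]
    lb[j] <- r$lb; ub[j] <- r$ub
    gpr[j] <- if (is.null(r$gpr)) "" else r$gpr
  }
  MetabolicModel(metabolites = mets, reactions = names(rxns), S = S,
                 lb = lb, ub = ub, gpr = gpr, genes = genes,
                 objective = objective)
}

#' Generate a toy metabolic network
#'
#' * `chain`: uptake (bound 10) -> A -> B -> biomass; the FBA optimum equals
#'   the uptake bound.
#' * `branched`: one precursor, two alternative conversion routes to the
#'   biomass precursor, each gated by its own gene (`g1`, `g2`) and each
#'   with capacity for the whole objective.
#' * `mini_tca`: cit -> icit -> akg -> succ -> fum -> mal fragment with
#'   citrate uptake and malate-coupled maintenance, gene-gated per step.
#' * `glutathione`: gthrd <-> gthox interconversion plus a gthrd -> 5oxpro
#'   branch, with a gthox-coupled maintenance objective.
#'
#' @param kind one of `"chain"`, `"branched"`, `"mini_tca"`,
#'   `"glutathione"`.
#' @return A validated [MetabolicModel-class].
#' @export
makeToyNetwork <- function(kind = c("chain", "branched", "mini_tca",
                                    "glutathione")) {
  kind <- match.arg(kind)
  m <- switch(kind,
    chain = toyModel(
      mets = c("A", "B"),
      rxns = list(
        uptake  = list(mets = c(A = 1), lb = 0, ub = 10),
        convert = list(mets = c(A = -1, B = 1), lb = 0, ub = 1000,
                       gpr = "g1"),
        biomass = list(mets = c(B = -1), lb = 0, ub = 1000)),
      objective = "biomass", genes = "g1"),
    branched = toyModel(
      mets = c("P", "Q"),
      rxns = list(
        uptake  = list(mets = c(P = 1), lb = 0, ub = 10),
        route1  = list(mets = c(P = -1, Q = 1), lb = 0, ub = 10,
                       gpr = "g1"),
        route2  = list(mets = c(P = -1, Q = 1), lb = 0, ub = 10,
                       gpr = "g2"),
        biomass = list(mets = c(Q = -1), lb = 0, ub = 10)),
      objective = "biomass", genes = c("g1", "g2")),
    mini_tca = toyModel(
      mets = c("cit", "icit", "akg", "succ", "fum", "mal"),
      rxns = list(
        EX_cit  = list(mets = c(cit = 1), lb = 0, ub = 10),
        ACONT   = list(mets = c(cit = -1, icit = 1), lb = 0, ub = 100,
                       gpr = "aco"),
        ICDH    = list(mets = c(icit = -1, akg = 1), lb = 0, ub = 100,
                       gpr = "idh"),
        AKGDH   = list(mets = c(akg = -1, succ = 1), lb = 0, ub = 100,
                       gpr = "ogdh"),
        SUCD    = list(mets = c(succ = -1, fum = 1), lb = 0, ub = 100,
                       gpr = "sdh"),
        FUM     = list(mets = c(fum = -1, mal = 1), lb = -100, ub = 100,
                       gpr = "fh"),
        maint   = list(mets = c(mal = -1), lb = 0, ub = 100)),
      objective = "maint",
      genes = c("aco", "idh", "ogdh", "sdh", "fh")),
    glutathione = toyModel(
      mets = c("gthrd", "gthox", "x5oxpro"),
      rxns = list(
        EX_gthrd = list(mets = c(gthrd = 1), lb = 0, ub = 10),
        GTHO     = list(mets = c(gthrd = -2, gthox = 1), lb = -100,
                        ub = 100, gpr = "gpx or gsr"),
        OXPRO    = list(mets = c(gthrd = -1, x5oxpro = 1), lb = 0,
                        ub = 100, gpr = "ggct"),
        EX_5oxp  = list(mets = c(x5oxpro = -1), lb = 0, ub = 100),
        maint    = list(mets = c(gthox = -1), lb = 0, ub = 100),
        EX_gthox = list(mets = c(gthox = -1), lb = 0, ub = 0)),
      objective = "maint",
      genes = c("gpx", "gsr", "ggct")))
  validateModel(m)
  m
}

#' Boolean expression profile from present genes
#'
#' Present genes get the value 100, every other model gene 0 — the boolean
#' presence scheme used to feed proteomics evidence into GIMME.
#'
#' @param model a [MetabolicModel-class].
#' @param presentGenes character set of observed genes; ids outside the
#'   model trigger a warning and are ignored.
#' @return An [ExpressionProfile-class] covering all model genes.
#' @export
makeExpressionProfile <- function(model, presentGenes = character(0)) {
  extra <- setdiff(presentGenes, model@genes)
  if (length(extra))
    warning("present gene(s) not in the model, ignored: ",
            paste(extra, collapse = ", "))
  v <- setNames(rep(0, length(model@genes)), model@genes)
  v[intersect(presentGenes, model@genes)] <- 100
  ExpressionProfile(v)
}
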