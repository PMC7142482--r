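#' Metabolic model input/output
#'
#' Two interchangeable on-disk representations are supported: a JSON dialect
#' field-compatible with the common constraint-based format
#' (`{metabolites:[{id}], reactions:[{id, metabolites:{id:coeff}, lb, ub,
#' gpr}], genes:[id], objective: id}`), and SBML Level 3 with the FBC
#' version 2 package (flux bounds as referenced parameters, gene products
#' and `fbc:and`/`fbc:or` associations, an active objective). Both
#' round-trip: `readModel(writeModel(m))` is structurally equal to `m`.
#' Genome-scale reconstructions in either format can be read; the in-memory
#' stoichiometric matrix is sparse.
#'
#' @name model-io
NULL

#' Write a metabolic model
#'
#' @param model a [MetabolicModel-class].
#' @param path output file.
#' @param format `"json"` or `"sbml"`.
#' @return Invisibly, `path`.
#' @export
writeModel <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (format == "json") writeModelJSON(model, path)
  else writeModelSBML(model, path)
  invisible(path)
}

#' Read a metabolic model
#'
#' @param path model file.
#' @param format `"json"` or `"sbml"`; guessed from the extension when
#'   missing (`.xml`/`.sbml` is SBML).
#' @return A validated [MetabolicModel-class].
#' @export
readModel <- function(path, format = c("json", "sbml")) {
  if (!file.exists(path)) stop("model file not found: ", path)
  format <- if (missing(format)) {
    if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  } else match.arg(format)
  m <- if (format == "json") readModelJSON(path) else readModelSBML(path)
  validateModel(m)
  m
}

writeModelJSON <- function(model, path) {
  S <- model@S
  rx <- lapply(seq_along(model@reactions), function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    list(id = model@reactions[j],
         metabolites = as.list(setNames(as.numeric(col[nz]),
                                        model@metabolites[nz])),
         lb = model@lb[j], ub = model@ub[j], gpr = model@gpr[j])
  })
  obj <- list(metabolites = lapply(model@metabolites,
                                   function(id) list(id = id)),
              reactions = rx,
              genes = as.list(model@genes),
              objective = model@objective)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

readModelJSON <- function(path) {
  j <- jsonlite::read_json(path)
  errs <- character(0)
  for (f in c("metabolites", "reactions", "objective"))
    if (is.null(j[[f]])) errs <- c(errs, paste0("missing field '", f, "'"))
  if (length(errs))
    stop("model JSON schema violations:\n  - ",
         paste(errs, collapse = "\n  - "))
  mets <- vapply(j$metabolites, function(m) as.character(m$id), character(1))
  rids <- vapply(j$reactions, function(r) as.character(r$id), character(1))
  S <- matrix(0, length(mets), length(rids),
              dimnames = list(mets, rids))
  lb <- ub <- numeric(length(rids)); gpr <- character(length(rids))
  for (k in seq_along(j$reactions)) {
    r <- j$reactions[[k]]
    for (f in c("lb", "ub"))
      if (is.null(r[[f]]))
        errs <- c(errs, sprintf("reaction '%s': missing bound '%s'",
                                r$id, f))
    for (mid in names(r$metabolites)) {
      if (!mid %in% mets)
        errs <- c(errs, sprintf("reaction '%s': unknown metabolite '%s'",
                                r$id, mid))
      else S[mid, k] <- as.numeric(r$metabolites[[mid]])
    }
    lb[k] <- if (is.null(r$lb)) NA_real_ else as.numeric(r$lb)
    ub[k] <- if (is.null(r$ub)) NA_real_ else as.numeric(r$ub)
    gpr[k] <- if (is.null(r$gpr)) "" else as.character(r$gpr)
  }
  if (length(errs))
    stop("model JSON schema violations:\n  - ",
         paste(errs, collapse = "\n  - "))
  MetabolicModel(metabolites = mets, reactions = rids, S = S, lb = lb,
                 ub = ub, gpr = gpr,
                 genes = vapply(j$genes, as.character, character(1)),
                 objective = as.character(j$objective))
}

# ---- SBML Level 3 + FBC v2 --------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

gprToFBC <- function(tree) {
  if (tree$op == "gene")
    return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>', tree$id))
  inner <- paste(vapply(tree$args, gprToFBC, character(1)), collapse = "")
  sprintf("<fbc:%s>%s</fbc:%s>", tree$op, inner, tree$op)
}

writeModelSBML <- function(model, path) {
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    '<model id="model" fbc:strict="true">',
    "<listOfCompartments>",
    '<compartment id="c" constant="true"/>',
    "</listOfCompartments>",
    "<listOfSpecies>",
    sprintf('<species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
            model@metabolites),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf('<parameter id="lb_%d" value="%s" constant="true"/>',
            seq_along(model@reactions), num(model@lb)),
    sprintf('<parameter id="ub_%d" value="%s" constant="true"/>',
            seq_along(model@reactions), num(model@ub)),
    "</listOfParameters>")
  S <- model@S
  for (j in seq_along(model@reactions)) {
    col <- S[, j]
    sub <- which(col < 0); prod <- which(col > 0)
    lines <- c(lines, sprintf(
      '<reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%d" fbc:upperFluxBound="ub_%d">',
      model@reactions[j], tolower(model@lb[j] < 0), j, j))
    tree <- parseGPR(model@gpr[j])
    if (!is.null(tree))
      lines <- c(lines,
                 "<fbc:geneProductAssociation>",
                 gprToFBC(tree),
                 "</fbc:geneProductAssociation>")
    if (length(sub))
      lines <- c(lines, "<listOfReactants>",
                 sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         model@metabolites[sub], num(-col[sub])),
                 "</listOfReactants>")
    if (length(prod))
      lines <- c(lines, "<listOfProducts>",
                 sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         model@metabolites[prod], num(col[prod])),
                 "</listOfProducts>")
    lines <- c(lines, "</reaction>")
  }
  # wrap the reaction blocks in listOfReactions
  insertAt <- which(lines == "</listOfParameters>")
  lines <- append(lines, "<listOfReactions>", after = insertAt)
  lines <- c(lines, "</listOfReactions>")
  if (length(model@genes)) {
    lines <- c(lines, "<fbc:listOfGeneProducts>",
               sprintf('<fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                       model@genes, model@genes),
               "</fbc:listOfGeneProducts>")
  }
  lines <- c(lines,
             '<fbc:listOfObjectives fbc:activeObjective="obj">',
             '<fbc:objective fbc:id="obj" fbc:type="maximize">',
             "<fbc:listOfFluxObjectives>",
             sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                     model@objective),
             "</fbc:listOfFluxObjectives>",
             "</fbc:objective>",
             "</fbc:listOfObjectives>",
             "</model>", "</sbml>")
  writeLines(lines, path)
}

fbcToGPRString <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef")
    return(xml2::xml_attr(node, "geneProduct"))
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, fbcToGPRString, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

readModelSBML <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  errs <- character(0)
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- xml2::xml_attr(species, "id")
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))
  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rids <- xml2::xml_attr(rnodes, "id")
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  lb <- ub <- numeric(length(rids)); gpr <- character(length(rids))
  for (j in seq_along(rnodes)) {
    rn <- rnodes[[j]]
    lbRef <- xml2::xml_attr(rn, "fbc:lowerFluxBound", ns)
    ubRef <- xml2::xml_attr(rn, "fbc:upperFluxBound", ns)
    if (is.na(lbRef) || is.na(ubRef)) {
      errs <- c(errs, sprintf(
        "reaction '%s': missing fbc:lowerFluxBound/fbc:upperFluxBound",
        rids[j]))
      next
    }
    if (!lbRef %in% names(pvals) || !ubRef %in% names(pvals)) {
      errs <- c(errs, sprintf(
        "reaction '%s': bound parameter '%s' or '%s' not declared",
        rids[j], lbRef, ubRef))
      next
    }
    lb[j] <- pvals[[lbRef]]; ub[j] <- pvals[[ubRef]]
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference",
                                  ns))
      S[xml2::xml_attr(sr, "species"), j] <-
        S[xml2::xml_attr(sr, "species"), j] -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference",
                                  ns))
      S[xml2::xml_attr(sr, "species"), j] <-
        S[xml2::xml_attr(sr, "species"), j] +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    gpa <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation/*", ns)
    gpr[j] <- if (inherits(gpa, "xml_missing")) "" else fbcToGPRString(gpa)
  }
  if (length(errs))
    stop("SBML-FBC validation errors:\n  - ",
         paste(errs, collapse = "\n  - "))
  genes <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns),
    "fbc:id", ns)
  fo <- xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns)
  if (inherits(fo, "xml_missing"))
    stop("SBML-FBC validation errors:\n  - missing fbc:fluxObjective")
  MetabolicModel(metabolites = mets, reactions = rids, S = S, lb = lb,
                 ub = ub, gpr = gpr, genes = genes,
                 objective = xml2::xml_attr(fo, "fbc:reaction", ns))
}
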