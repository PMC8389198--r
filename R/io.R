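#' Load a metabolic model from file
#'
#' Two formats are supported. `"json"` is the package's documented dialect:
#' one object with `metabolites`, `reactions` (stoichiometry as an
#' `{met_id: coefficient}` map), `genes`, `objective` and optional
#' `annotations`. `"sbml"` targets SBML Level 3 with the flux-balance
#' constraints (fbc) package; when fbc bounds are absent, bounds default to
#' +/-1000 (0 for the lower bound of irreversible reactions) with a warning.
#'
#' @param path file to read.
#' @param format `"json"` or `"sbml"`; default guessed from the extension.
#' @return A validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format, json = load_model_json(path), sbml = load_model_sbml(path))
}

#' Save a metabolic model to file
#'
#' Round-trip contract: `load_model(save_model(m, p), fmt)` reproduces `m`
#' field-wise, with reaction and metabolite order preserved and floating-point
#' bounds reproduced to full precision.
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @param format `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  validate_model(model)
  switch(format,
         json = save_model_json(model, path),
         sbml = save_model_sbml(model, path))
  invisible(path)
}

load_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("JSON format error in '", path, "': ",
                             conditionMessage(e)))
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c",
               formula = m$formula %||% NA_character_,
               charge = m$charge %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    st <- stats::setNames(as.numeric(st), names(st))
    reaction(id = r$id, name = r$name %||% r$id,
             stoichiometry = st,
             lower_bound = as.numeric(r$lower_bound %||% -1000),
             upper_bound = as.numeric(r$upper_bound %||% 1000),
             subsystem = r$subsystem %||% "",
             gene_rule = r$gene_rule %||% "",
             is_exchange = r$is_exchange %||% NA,
             is_lumped = r$is_lumped %||% NA)
  })
  metabolic_model(mets, rxns,
                  genes = unlist(doc$genes) %||% character(),
                  objective_id = doc$objective,
                  annotations = doc$annotations %||% list())
}

save_model_json <- function(model, path) {
  doc <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$charge)) out$charge <- m$charge
      out
    }),
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, name = r$name,
           stoichiometry = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           subsystem = r$subsystem, gene_rule = r$gene_rule,
           is_exchange = r$is_exchange, is_lumped = r$is_lumped)
    }),
    genes = model$genes,
    objective = model$objective_id,
    annotations = model$annotations)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE)
  writeLines(json, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sbml_ns <- c(
  core = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

xml_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

num_attr <- function(x) sprintf("%.17g", x)

save_model_sbml <- function(model, path) {
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), sbml_ns["core"], sbml_ns["fbc"]),
    '  <model id="model" fbc:strict="true">')
  comps <- unique(model$metabolites$compartment)
  out <- c(out, "    <listOfCompartments>",
           sprintf('      <compartment id="%s" constant="true"/>',
                   xml_esc(comps)),
           "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    extra <- ""
    if (!is.na(m$formula)) {
      extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"',
                                     xml_esc(m$formula)))
    }
    if (!is.na(m$charge)) {
      extra <- paste0(extra, sprintf(' fbc:charge="%d"', as.integer(m$charge)))
    }
    out <- c(out, sprintf(
      paste0('      <species id="M_%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"%s/>'),
      xml_esc(m$id), xml_esc(m$name), xml_esc(m$compartment), extra))
  }
  out <- c(out, "    </listOfSpecies>", "    <listOfParameters>")
  for (r in model$reactions) {
    out <- c(out,
             sprintf('      <parameter id="R_%s_lb" value="%s" constant="true"/>',
                     xml_esc(r$id), num_attr(r$lower_bound)),
             sprintf('      <parameter id="R_%s_ub" value="%s" constant="true"/>',
                     xml_esc(r$id), num_attr(r$upper_bound)))
  }
  out <- c(out, "    </listOfParameters>", "    <listOfReactions>")
  for (r in model$reactions) {
    rid <- xml_esc(r$id)
    out <- c(out, sprintf(
      paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="R_%s_lb" fbc:upperFluxBound="R_%s_ub">'),
      rid, xml_esc(r$name), tolower(r$lower_bound < 0), rid, rid))
    notes <- c(sprintf("SUBSYSTEM: %s", r$subsystem),
               sprintf("GENE_ASSOCIATION: %s", r$gene_rule),
               sprintf("IS_EXCHANGE: %s", r$is_exchange),
               sprintf("IS_LUMPED: %s", r$is_lumped))
    out <- c(out, "        <notes>",
             '          <body xmlns="http://www.w3.org/1999/xhtml">',
             sprintf("            <p>%s</p>", xml_esc(notes)),
             "          </body>", "        </notes>")
    st <- r$stoichiometry
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      out <- c(out, "        <listOfReactants>",
               sprintf(paste0('          <speciesReference species="M_%s" ',
                              'stoichiometry="%s" constant="true"/>'),
                       xml_esc(names(reac)), num_attr(-unname(reac))),
               "        </listOfReactants>")
    }
    if (length(prod)) {
      out <- c(out, "        <listOfProducts>",
               sprintf(paste0('          <speciesReference species="M_%s" ',
                              'stoichiometry="%s" constant="true"/>'),
                       xml_esc(names(prod)), num_attr(unname(prod))),
               "        </listOfProducts>")
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>")
  if (length(model$genes)) {
    out <- c(out, "    <fbc:listOfGeneProducts>",
             sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                     xml_esc(model$genes), xml_esc(model$genes)),
             "    </fbc:listOfGeneProducts>")
  }
  out <- c(out,
           '    <fbc:listOfObjectives fbc:activeObjective="obj">',
           '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
           "        <fbc:listOfFluxObjectives>",
           sprintf(paste0('          <fbc:fluxObjective fbc:reaction="R_%s" ',
                          'fbc:coefficient="1"/>'),
                   xml_esc(model$objective_id)),
           "        </fbc:listOfFluxObjectives>",
           "      </fbc:objective>",
           "    </fbc:listOfObjectives>",
           "  </model>", "</sbml>")
  writeLines(out, path)
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

note_field <- function(notes, key) {
  hit <- grep(paste0("^", key, ": ?"), notes, value = TRUE)
  if (!length(hit)) return(NULL)
  sub(paste0("^", key, ": ?"), "", hit[1])
}

load_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML format error in '", path,
                                           "': ", conditionMessage(e)))
  ns <- xml2::xml_ns(doc)
  has_fbc <- any(unlist(ns) == sbml_ns[["fbc"]])
  fbc_pfx <- if (has_fbc) names(ns)[unlist(ns) == sbml_ns[["fbc"]]][1]
  core_pfx <- names(ns)[unlist(ns) == sbml_ns[["core"]]][1]
  if (is.na(core_pfx) || !length(core_pfx)) {
    stop("SBML format error in '", path, "': not an SBML Level 3 document")
  }
  q <- function(tag) sprintf(".//%s:%s", core_pfx, tag)

  sp <- xml2::xml_find_all(doc, q("species"), ns)
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = if (has_fbc) xml2::xml_attr(sp, "chemicalFormula")
      else NA_character_,
    charge = if (has_fbc)
      as.integer(xml2::xml_attr(sp, "charge")) else NA_integer_,
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  pars <- xml2::xml_find_all(doc, q("parameter"), ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  warned <- FALSE
  rn <- xml2::xml_find_all(doc, q("reaction"), ns)
  rxns <- lapply(rn, function(node) {
    rid <- strip_prefix(xml2::xml_attr(node, "id"), "R_")
    rname <- xml2::xml_attr(node, "name")
    if (is.na(rname)) rname <- rid
    getsp <- function(tag, sgn) {
      refs <- xml2::xml_find_all(
        node, sprintf("./%s:%s/%s:speciesReference", core_pfx, tag, core_pfx),
        ns)
      if (!length(refs)) return(numeric())
      stats::setNames(
        sgn * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
        strip_prefix(xml2::xml_attr(refs, "species"), "M_"))
    }
    st <- c(getsp("listOfReactants", -1), getsp("listOfProducts", 1))
    lb_ref <- if (has_fbc) xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- if (has_fbc) xml2::xml_attr(node, "upperFluxBound")
    if (is.null(lb_ref) || is.na(lb_ref) || !lb_ref %in% names(parval)) {
      if (!warned) {
        warning("no fbc flux bounds in '", path,
                "'; applying default bounds", call. = FALSE)
        warned <<- TRUE
      }
      rev <- identical(xml2::xml_attr(node, "reversible"), "true")
      lb <- if (rev) -1000 else 0
      ub <- 1000
    } else {
      lb <- parval[[lb_ref]]
      ub <- parval[[ub_ref]]
    }
    notes <- xml2::xml_text(xml2::xml_find_all(
      node, sprintf('./%s:notes//*[local-name()="p"]', core_pfx), ns))
    reaction(id = rid, name = rname, stoichiometry = st,
             lower_bound = lb, upper_bound = ub,
             subsystem = note_field(notes, "SUBSYSTEM") %||% "",
             gene_rule = note_field(notes, "GENE_ASSOCIATION") %||% "",
             is_exchange = as.logical(note_field(notes, "IS_EXCHANGE") %||%
                                        NA),
             is_lumped = as.logical(note_field(notes, "IS_LUMPED") %||% NA))
  })

  genes <- character()
  if (has_fbc) {
    gp <- xml2::xml_find_all(doc, sprintf(".//%s:geneProduct", fbc_pfx), ns)
    genes <- strip_prefix(xml2::xml_attr(gp, "id"), "G_")
  }
  obj_id <- NULL
  if (has_fbc) {
    fo <- xml2::xml_find_first(doc, sprintf(".//%s:fluxObjective", fbc_pfx),
                               ns)
    if (!inherits(fo, "xml_missing")) {
      obj_id <- strip_prefix(xml2::xml_attr(fo, "reaction"), "R_")
    }
  }
  if (is.null(obj_id)) {
    obj_id <- strip_prefix(xml2::xml_attr(rn[[1]], "id"), "R_")
    warning("no fbc objective in '", path, "'; using first reaction '",
            obj_id, "'", call. = FALSE)
  }
  metabolic_model(mets, rxns, genes = genes, objective_id = obj_id)
}
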