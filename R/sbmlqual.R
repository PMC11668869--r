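## SBML Level 3 + qual package I/O.
##
## The reader targets the dialect emitted by logical-model converters such
## as CaSQ: one transition per target species, function terms in MathML
## restricted to and/or/not over <ci> species (plus eq/geq/leq comparisons
## against 0/1 constants). Transitions that carry no listOfFunctionTerms at
## all are treated as sign-only: the rule "OR of activators AND NOT OR of
## inhibitors" is synthesized from the qual:sign input attributes, with a
## warning.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
QUAL_NS <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
ANN_NS <- "urn:mcboolnet:identifiers"

## namespaced attribute lookup: try the qual-qualified name, fall back to
## the bare name (some emitters leave qual attributes unprefixed)
qattr <- function(node, attr, ns) {
  v <- xml2::xml_attr(node, paste0("qual:", attr), ns = ns)
  bare <- xml2::xml_attr(node, attr)
  ifelse(is.na(v), bare, v)
}

#' Read an SBML-qual logical model
#'
#' Parses an SBML Level 3 file using the qualitative-models package into a
#' [boolean_model()]. Qualitative species with no incoming transition
#' become inputs; transitions whose function terms reduce to a constant
#' become constant rules. Only Boolean models are supported: a species
#' with `maxLevel > 1` is rejected.
#'
#' @param path path to an SBML-qual file.
#' @return a `boolean_model`.
#' @export
read_sbmlqual <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed XML in '", path, "': ", conditionMessage(e))
  })
  ns <- c(sbml = SBML_NS, qual = QUAL_NS, m = MATHML_NS)

  sp <- xml2::xml_find_all(doc, ".//qual:qualitativeSpecies", ns)
  if (!length(sp)) {
    # degenerate but legal: a model with no qualitative species
    return(boolean_model(nodes = character(0)))
  }
  ids <- qattr(sp, "id", ns)
  if (anyDuplicated(ids)) stop("duplicate qualitativeSpecies ids in '", path, "'")
  maxlev <- qattr(sp, "maxLevel", ns)
  multi <- !is.na(maxlev) & suppressWarnings(as.numeric(maxlev)) > 1
  if (any(multi)) {
    stop("unsupported multi-valued species (maxLevel > 1): ",
         paste(ids[multi], collapse = ", "))
  }
  labels <- qattr(sp, "name", ns)
  names(labels) <- ids
  labels <- labels[!is.na(labels)]

  annotations <- list()
  for (i in seq_along(sp)) {
    idents <- xml2::xml_find_all(
      sp[[i]], ".//ann:identifier", c(ann = ANN_NS))
    if (length(idents)) {
      annotations[[ids[[i]]]] <- xml2::xml_attr(idents, "value")
    }
  }

  rules <- list()
  trans <- xml2::xml_find_all(doc, ".//qual:transition", ns)
  for (tr in trans) {
    out <- xml2::xml_find_first(tr, ".//qual:listOfOutputs/qual:output", ns)
    if (inherits(out, "xml_missing")) stop("transition without output in '", path, "'")
    target <- qattr(out, "qualitativeSpecies", ns)
    if (!(target %in% ids)) {
      stop("transition output references undeclared species '", target, "'")
    }
    fterms <- xml2::xml_find_first(tr, ".//qual:listOfFunctionTerms", ns)
    if (inherits(fterms, "xml_missing")) {
      rules[[target]] <- sign_rule_from_inputs(tr, ns, target, ids)
    } else {
      rules[[target]] <- rule_from_function_terms(fterms, ns, ids, target)
    }
  }
  boolean_model(nodes = ids, rules = rules,
                annotations = annotations, labels = labels)
}

## Synthesize "OR(activators) & !OR(inhibitors)" from sign-only inputs.
sign_rule_from_inputs <- function(tr, ns, target, ids) {
  warning("transition for '", target,
          "' has no function terms; synthesizing rule from input signs",
          call. = FALSE)
  inp <- xml2::xml_find_all(tr, ".//qual:listOfInputs/qual:input", ns)
  regs <- qattr(inp, "qualitativeSpecies", ns)
  signs <- qattr(inp, "sign", ns)
  missing <- setdiff(regs, ids)
  if (length(missing)) {
    stop("transition input references undeclared species: ",
         paste(missing, collapse = ", "))
  }
  signs[is.na(signs)] <- "positive"
  act <- regs[signs != "negative"]
  inh <- regs[signs == "negative"]
  or_join <- function(v) Reduce(function(a, b) call("|", a, b),
                                lapply(v, as.symbol))
  rule <- NULL
  if (length(act)) rule <- or_join(act)
  if (length(inh)) {
    neg <- call("!", call("(", or_join(inh)))
    rule <- if (is.null(rule)) neg else call("&", call("(", rule), neg)
  }
  if (is.null(rule)) TRUE else rule
}

rule_from_function_terms <- function(fterms, ns, ids, target) {
  dflt <- xml2::xml_find_first(fterms, ".//qual:defaultTerm", ns)
  dlevel <- if (inherits(dflt, "xml_missing")) 0L else
    as.integer(qattr(dflt, "resultLevel", ns))
  terms <- xml2::xml_find_all(fterms, ".//qual:functionTerm", ns)
  if (!length(terms)) return(dlevel == 1L)  # constant rule
  levels <- as.integer(qattr(terms, "resultLevel", ns))
  maths <- lapply(terms, function(t) {
    mnode <- xml2::xml_find_first(t, ".//m:math/*", ns)
    if (inherits(mnode, "xml_missing")) {
      stop("functionTerm for '", target, "' has no MathML body")
    }
    parse_mathml(mnode, ids, target)
  })
  wanted <- if (dlevel == 0L) maths[levels == 1L] else maths[levels == 0L]
  if (!length(wanted)) return(dlevel == 1L)
  expr <- Reduce(function(a, b) call("|", call("(", a), call("(", b)), wanted)
  if (dlevel == 0L) expr else call("!", call("(", expr))
}

## Parse a MathML node into an R logic expression over species ids.
parse_mathml <- function(node, ids, target) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") {
    id <- trimws(xml2::xml_text(node))
    if (!(id %in% ids)) {
      stop("function term for '", target,
           "' references undeclared species '", id, "'")
    }
    return(as.symbol(id))
  }
  if (nm == "cn") {
    v <- suppressWarnings(as.numeric(trimws(xml2::xml_text(node))))
    return(!is.na(v) && v >= 1)
  }
  if (nm == "true") return(TRUE)
  if (nm == "false") return(FALSE)
  if (nm != "apply") stop("unsupported MathML element <", nm, "> in rule for '",
                          target, "'")
  children <- xml2::xml_children(node)
  op <- xml2::xml_name(children[[1]])
  args <- lapply(children[-1], parse_mathml, ids = ids, target = target)
  join <- function(fun) Reduce(function(a, b) call(fun, a, b), args)
  switch(op,
    "and" = join("&"),
    "or" = join("|"),
    "not" = call("!", wrap_paren(args[[1]])),
    "eq" = , "geq" = mathml_compare(children, args, negate = FALSE, target = target),
    "leq" = , "lt" = mathml_compare(children, args, negate = TRUE, target = target),
    stop("unsupported MathML operator <", op, "> in rule for '", target, "'")
  )
}

wrap_paren <- function(e) if (is.call(e)) call("(", e) else e

## <apply><eq/><ci>A</ci><cn>1</cn></apply>  ->  A   (geq 1 likewise)
## eq against 0, or leq/lt thresholds  ->  !A
mathml_compare <- function(children, args, negate, target) {
  sym <- Filter(function(a) is.symbol(a), args)
  cst <- Filter(function(a) is.logical(a), args)
  if (length(sym) != 1L || length(cst) != 1L) {
    stop("unsupported comparison in rule for '", target, "'")
  }
  positive <- if (negate) !cst[[1]] else cst[[1]]
  if (positive) sym[[1]] else call("!", sym[[1]])
}

#' Write a Boolean model as SBML-qual
#'
#' Emits SBML Level 3 Version 1 with the qual package: one qualitative
#' species per node (`maxLevel = 1`) and one transition per rule-bearing
#' node, with the rule encoded as a MathML function term
#' (`resultLevel = 1`) over `and`/`or`/`not`. Constant rules become a
#' transition whose default term carries the constant. Annotations are
#' stored as a plain identifier list inside each species' `<annotation>`
#' element so that `read_sbmlqual(write_sbmlqual(m))` restores them.
#'
#' @param model a `boolean_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbmlqual <- function(model, path) {
  stopifnot(inherits(model, "boolean_model"))
  for (n in names(model$rules)) {
    missing <- setdiff(rule_regulators(model$rules[[n]]), model$nodes)
    if (length(missing)) {
      stop("rule for '", n, "' references unknown node(s): ",
           paste(missing, collapse = ", "))
    }
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"", SBML_NS, "\" level=\"3\" version=\"1\" ",
           "xmlns:qual=\"", QUAL_NS, "\" qual:required=\"true\">"),
    "  <model id=\"model\">",
    "    <listOfCompartments>",
    "      <compartment id=\"default\" constant=\"true\"/>",
    "    </listOfCompartments>",
    "    <qual:listOfQualitativeSpecies>"
  )
  for (n in model$nodes) {
    attrs <- paste0("qual:id=\"", esc(n), "\" qual:compartment=\"default\" ",
                    "qual:constant=\"false\" qual:maxLevel=\"1\"")
    lab <- model$labels[n]
    if (!is.na(lab) && !is.null(lab) && length(lab)) {
      attrs <- paste0(attrs, " qual:name=\"", esc(unname(lab)), "\"")
    }
    ann <- model$annotations[[n]]
    if (length(ann)) {
      lines <- c(lines,
        paste0("      <qual:qualitativeSpecies ", attrs, ">"),
        "        <annotation>",
        paste0("          <identifiers xmlns=\"", ANN_NS, "\">"),
        paste0("            <identifier value=\"", esc(ann), "\"/>"),
        "          </identifiers>",
        "        </annotation>",
        "      </qual:qualitativeSpecies>")
    } else {
      lines <- c(lines, paste0("      <qual:qualitativeSpecies ", attrs, "/>"))
    }
  }
  lines <- c(lines, "    </qual:listOfQualitativeSpecies>",
             "    <qual:listOfTransitions>")
  for (n in names(model$rules)) {
    rule <- model$rules[[n]]
    regs <- rule_regulators(rule)
    lines <- c(lines, paste0("      <qual:transition qual:id=\"tr_", esc(n), "\">"))
    if (length(regs)) {
      lines <- c(lines, "        <qual:listOfInputs>")
      for (r in regs) {
        lines <- c(lines, paste0(
          "          <qual:input qual:qualitativeSpecies=\"", esc(r),
          "\" qual:transitionEffect=\"none\"/>"))
      }
      lines <- c(lines, "        </qual:listOfInputs>")
    }
    lines <- c(lines,
      "        <qual:listOfOutputs>",
      paste0("          <qual:output qual:qualitativeSpecies=\"", esc(n),
             "\" qual:transitionEffect=\"assignmentLevel\"/>"),
      "        </qual:listOfOutputs>",
      "        <qual:listOfFunctionTerms>")
    if (is.logical(rule)) {
      lines <- c(lines, paste0(
        "          <qual:defaultTerm qual:resultLevel=\"",
        if (rule) "1" else "0", "\"/>"))
    } else {
      lines <- c(lines,
        "          <qual:defaultTerm qual:resultLevel=\"0\"/>",
        "          <qual:functionTerm qual:resultLevel=\"1\">",
        paste0("            <math xmlns=\"", MATHML_NS, "\">"),
        rule_to_mathml(rule, indent = "              "),
        "            </math>",
        "          </qual:functionTerm>")
    }
    lines <- c(lines,
      "        </qual:listOfFunctionTerms>",
      "      </qual:transition>")
  }
  lines <- c(lines,
    "    </qual:listOfTransitions>",
    "  </model>",
    "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

rule_to_mathml <- function(rule, indent = "") {
  if (is.logical(rule)) {
    return(paste0(indent, if (rule) "<true/>" else "<false/>"))
  }
  if (is.symbol(rule)) {
    return(paste0(indent, "<ci> ", as.character(rule), " </ci>"))
  }
  op <- as.character(rule[[1]])
  if (op == "(") return(rule_to_mathml(rule[[2]], indent))
  tag <- switch(op, "&" = , "&&" = "and", "|" = , "||" = "or", "!" = "not",
                stop("cannot serialize operator '", op, "' to MathML"))
  args <- as.list(rule)[-1]
  c(paste0(indent, "<apply>"),
    paste0(indent, "  <", tag, "/>"),
    unlist(lapply(args, rule_to_mathml, indent = paste0(indent, "  "))),
    paste0(indent, "</apply>"))
}
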