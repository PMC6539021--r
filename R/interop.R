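# ---- ontology trees --------------------------------------------------------

#' Ontology node
#'
#' One node of the hierarchical attribute tree built from a dataset or a
#' FHIR resource: a dot-separated path name, child nodes (the
#' relationships), and example instance values attached to leaves.
#'
#' @param name dot-separated attribute path (e.g. `"patient.identifier"`)
#' @param children list of child `ontology_node`s
#' @param instances character vector of example values (leaves)
#' @return object of class `ontology_node`
#' @export
ontology_node <- function(name, children = list(), instances = character()) {
  structure(list(name = name, children = children, instances = instances),
            class = "ontology_node")
}

build_node <- function(x, path) {
  kids <- xml2::xml_children(x)
  if (length(kids) == 0) {
    txt <- trimws(xml2::xml_text(x))
    return(ontology_node(path, instances = if (nzchar(txt)) txt else character()))
  }
  children <- list()
  for (k in kids) {
    cname <- xml2::xml_name(k)
    cpath <- paste(c(path, cname), collapse = ".")
    child <- build_node(k, cpath)
    children[[cname]] <- if (is.null(children[[cname]])) child
                         else merge_nodes(children[[cname]], child)
  }
  ontology_node(path, children = children)
}

# repeated elements collapse into one node per distinct path, recursively
merge_nodes <- function(a, b) {
  a$instances <- c(a$instances, b$instances)
  for (nm in names(b$children)) {
    a$children[[nm]] <- if (is.null(a$children[[nm]])) b$children[[nm]]
                        else merge_nodes(a$children[[nm]], b$children[[nm]])
  }
  a
}

#' Build an ontology tree from an XML document
#'
#' One node per distinct element path; leaf text content becomes the node's
#' instances; repeated elements merge into a single node (their instances
#' accumulate). Traversal is document order, so the result is deterministic.
#'
#' @param doc an `xml2::xml_document`, or a path to an XML file
#' @return the root `ontology_node`
#' @export
build_ontology <- function(doc) {
  if (is.character(doc)) {
    doc <- tryCatch(xml2::read_xml(doc),
                    error = function(e) stopf("cannot parse XML: %s",
                                              conditionMessage(e)))
  }
  root <- xml2::xml_root(doc)
  build_node(root, xml2::xml_name(root))
}

#' All attribute paths of an ontology tree
#'
#' @param node an `ontology_node`
#' @return character vector of dot-separated paths, depth-first
#' @export
ontology_paths <- function(node) {
  c(node$name, unlist(lapply(node$children, ontology_paths), use.names = FALSE))
}

find_node <- function(node, path) {
  if (identical(node$name, path)) return(node)
  for (ch in node$children) {
    hit <- find_node(ch, path)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' @export
print.ontology_node <- function(x, ...) {
  show <- function(n, indent) {
    inst <- if (length(n$instances) > 0)
      paste0(" [", paste(utils::head(n$instances, 3), collapse = ", "), "]") else ""
    cat(strrep("  ", indent), n$name, inst, "\n", sep = "")
    for (ch in n$children) show(ch, indent + 1)
  }
  show(x, 0)
  invisible(x)
}

# ---- structural similarity -------------------------------------------------

#' Overlapping character bigrams of an attribute name
#'
#' The name is upper-cased and split into tokens at every non-alphanumeric
#' character (so path segments like `patient.identifier` are tokenized
#' separately); each token contributes its adjacent overlapping character
#' pairs. Multiset semantics: repeated pairs are kept.
#'
#' @param name attribute name
#' @return character vector of bigrams (possibly with duplicates)
#' @export
bigram_pairs <- function(name) {
  if (is_blank(name)) return(character())
  tokens <- strsplit(toupper(name), "[^A-Z0-9]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  unlist(lapply(tokens, function(tk) {
    n <- nchar(tk)
    if (n < 2) return(character())
    vapply(seq_len(n - 1), function(i) substr(tk, i, i + 1), "")
  }), use.names = FALSE)
}

multiset_intersection <- function(a, b) {
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (length(common) == 0) return(0)
  sum(pmin(ta[common], tb[common]))
}

#' Structural similarity of two attribute names
#'
#' The Sørensen–Dice coefficient over bigram multisets:
#' `2 |pairs(a) n pairs(b)| / (|pairs(a)| + |pairs(b)|)`. Identical names
#' score 1 (case-insensitively); names sharing no bigram score 0.
#'
#' @param a,b attribute names (non-empty)
#' @return fraction in \[0, 1\]
#' @export
structural_similarity <- function(a, b) {
  pa <- bigram_pairs(a); pb <- bigram_pairs(b)
  if (length(pa) + length(pb) == 0) {
    warnf("no character pairs in either name ('%s', '%s'); similarity 0", a, b)
    return(0)
  }
  2 * multiset_intersection(pa, pb) / (length(pa) + length(pb))
}

# ---- semantic similarity ---------------------------------------------------

#' Bundled token-lexicon semantic backend
#'
#' A small pluggable stand-in for a distributed-semantics service: two terms
#' match when they are equal (case-insensitive) or share a synonym set in
#' the bundled lexicon of clinical-attribute vocabulary (patient/subject,
#' value/quantity/measured, date/time/effective, ...). Any object with a
#' `matches(term_a, term_b)` function can serve as a backend.
#'
#' @param extra optional list of additional synonym character vectors
#' @return a semantic backend (list with a `matches` predicate)
#' @export
lexicon_backend <- function(extra = list()) {
  synonyms <- c(list(
    c("patient", "subject", "person"),
    c("practitioner", "performer", "clinician", "doctor"),
    c("value", "quantity", "measured", "measurement", "result"),
    c("date", "time", "datetime", "effective", "instant", "when"),
    c("identifier", "id", "code"),
    c("name", "label", "title"),
    c("status", "state"),
    c("category", "class", "type", "group"),
    c("observation", "measurement", "reading"),
    c("unit", "uom"),
    c("report", "document")
  ), extra)
  matches <- function(a, b) {
    a <- tolower(a); b <- tolower(b)
    if (identical(a, b)) return(TRUE)
    any(vapply(synonyms, function(s) a %in% s && b %in% s, TRUE))
  }
  structure(list(matches = matches, synonyms = synonyms),
            class = "semantic_backend")
}

# camelCase / dot / dash tokenizer for semantic term comparison
semantic_tokens <- function(name) {
  x <- gsub("([a-z0-9])([A-Z])", "\\1 \\2", name)
  tokens <- tolower(strsplit(x, "[^A-Za-z0-9]+")[[1]])
  tokens[nzchar(tokens)]
}

# the (names, relationships, instances) triple of a node, flattened to terms
node_triples <- function(node) {
  rel <- vapply(node$children, function(ch) {
    parts <- strsplit(ch$name, ".", fixed = TRUE)[[1]]
    parts[length(parts)]
  }, "")
  list(names = semantic_tokens(node$name),
       relationships = unlist(lapply(unname(rel), semantic_tokens), use.names = FALSE),
       instances = as.character(node$instances))
}

#' Harmonic mean of precision and recall
#'
#' The F-measure; defined as 0 when both inputs are 0.
#'
#' @param precision,recall fractions in \[0, 1\]
#' @return fraction in \[0, 1\]
#' @export
f_measure <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Semantic similarity of two ontology nodes
#'
#' Both nodes are flattened to their (name tokens, relationship names,
#' instance values) triples. `a`'s terms are the proposed matches and `b`'s
#' the reference: precision is the fraction of `a`'s terms with a match in
#' `b` under the backend's predicate, recall the fraction of `b`'s terms
#' with a match in `a`, and the similarity is their harmonic mean (0 when
#' nothing matches).
#'
#' @param a,b `ontology_node`s
#' @param backend a semantic backend (default [lexicon_backend()]); an
#'   unusable backend falls back to the bundled lexicon with a warning
#' @return fraction in \[0, 1\]
#' @export
semantic_similarity <- function(a, b, backend = lexicon_backend()) {
  if (!is.function(backend$matches)) {
    warnf("semantic backend lacks a matches() predicate; using bundled lexicon")
    backend <- lexicon_backend()
  }
  ta <- node_triples(a); tb <- node_triples(b)
  terms_a <- unique(unlist(ta, use.names = FALSE))
  terms_b <- unique(unlist(tb, use.names = FALSE))
  if (length(terms_a) == 0 || length(terms_b) == 0) return(0)
  hit_a <- vapply(terms_a, function(x)
    any(vapply(terms_b, function(y) backend$matches(x, y), TRUE)), TRUE)
  hit_b <- vapply(terms_b, function(y)
    any(vapply(terms_a, function(x) backend$matches(x, y), TRUE)), TRUE)
  f_measure(sum(hit_a) / length(terms_a), sum(hit_b) / length(terms_b))
}

# ---- overall mapping -------------------------------------------------------

#' Overall similarity of a structural / semantic score pair
#'
#' The arithmetic mean `(St_Simil + Sem_Simil) / 2`, exact.
#'
#' @param st,sem fractions in \[0, 1\]
#' @return fraction in \[0, 1\]
#' @export
overall_similarity <- function(st, sem) {
  stopifnot(all(st >= 0 & st <= 1), all(sem >= 0 & sem <= 1))
  (st + sem) / 2
}

#' Map dataset attributes onto FHIR attributes
#'
#' Joins the structural and semantic similarity tables over all
#' (dataset attribute, candidate) pairs — a pair absent from one table
#' scores 0 in that channel — and computes the overall mean per pair. For
#' each dataset attribute, a candidate whose mean strictly exceeds the
#' threshold is selected (`above_threshold`); otherwise the candidate with
#' the maximal mean wins (`argmax_fallback`), ties broken lexicographically
#' by FHIR attribute name.
#'
#' @param st_table,sem_table data frames with columns `dataset_attr`,
#'   `fhir_attr`, `score` (fractions in \[0, 1\])
#' @param catalogue optional character vector of FHIR attribute names; used
#'   to resolve the degenerate all-zero case (must be non-empty if given)
#' @param threshold selection threshold as a fraction (default 0.9)
#' @return object of class `mapping_result`: the selection data frame
#'   (`dataset_attr`, `fhir_attr`, `mean`, `decision`) plus the full
#'   similarity `table`
#' @export
map_attributes <- function(st_table, sem_table, catalogue = NULL, threshold = 0.9) {
  if (!is.null(catalogue) && length(catalogue) == 0)
    stopf("empty FHIR attribute catalogue")
  key <- function(d) paste(d$dataset_attr, d$fhir_attr, sep = "\r")
  pairs <- unique(rbind(st_table[, c("dataset_attr", "fhir_attr")],
                        sem_table[, c("dataset_attr", "fhir_attr")]))
  pairs$st <- st_table$score[match(key(pairs), key(st_table))]
  pairs$sem <- sem_table$score[match(key(pairs), key(sem_table))]
  pairs$st[is.na(pairs$st)] <- 0
  pairs$sem[is.na(pairs$sem)] <- 0
  pairs$mean <- overall_similarity(pairs$st, pairs$sem)
  pairs <- pairs[order(pairs$dataset_attr, pairs$fhir_attr), , drop = FALSE]
  rownames(pairs) <- NULL

  sel <- do.call(rbind, lapply(split(pairs, pairs$dataset_attr), function(p) {
    over <- p[p$mean > threshold, , drop = FALSE]
    if (nrow(over) > 0) {
      best <- over[order(-over$mean, over$fhir_attr)[1], , drop = FALSE]
      decision <- "above_threshold"
    } else {
      best <- p[order(-p$mean, p$fhir_attr)[1], , drop = FALSE]
      decision <- "argmax_fallback"
    }
    flagged <- all(p$mean == 0)
    if (flagged && !is.null(catalogue)) {
      best$fhir_attr <- sort(catalogue)[1]
      best$mean <- 0
    }
    data.frame(dataset_attr = best$dataset_attr, fhir_attr = best$fhir_attr,
               mean = best$mean, decision = decision, flagged = flagged,
               stringsAsFactors = FALSE)
  }))
  rownames(sel) <- NULL
  structure(list(selection = sel, table = pairs, threshold = threshold),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("<mapping_result> %d attributes (threshold %.0f%%)\n",
              nrow(x$selection), 100 * x$threshold))
  print(x$selection, row.names = FALSE)
  invisible(x)
}

#' Match a dataset ontology against a FHIR attribute catalogue
#'
#' Computes the structural ([structural_similarity()]) and semantic
#' ([semantic_similarity()]) similarity of every dataset attribute against
#' every catalogue attribute, then selects per-attribute matches with
#' [map_attributes()].
#'
#' @param ds_tree dataset ontology root (`ontology_node`)
#' @param catalogue character vector of FHIR attribute names, e.g.
#'   [fhir_catalogue()]
#' @param backend semantic backend (default [lexicon_backend()])
#' @param threshold selection threshold fraction (default 0.9)
#' @param skip_root drop the tree root and structural scaffolding nodes
#'   (those without instances or with children) from the attribute list?
#'   Default `FALSE`: every named path except the root is matched.
#' @return a `mapping_result`
#' @export
match_dataset <- function(ds_tree, catalogue, backend = lexicon_backend(),
                          threshold = 0.9, skip_root = FALSE) {
  if (length(catalogue) == 0) stopf("empty FHIR attribute catalogue")
  paths <- setdiff(ontology_paths(ds_tree), ds_tree$name)
  # attribute names relative to the root element
  rel <- sub(paste0("^", ds_tree$name, "\\."), "", paths)
  st <- expand.grid(dataset_attr = rel, fhir_attr = catalogue,
                    stringsAsFactors = FALSE)
  st$score <- mapply(structural_similarity, st$dataset_attr, st$fhir_attr)
  sem <- st[, c("dataset_attr", "fhir_attr")]
  cat_nodes <- lapply(catalogue, ontology_node)
  names(cat_nodes) <- catalogue
  ds_nodes <- lapply(paths, function(p) find_node(ds_tree, p))
  names(ds_nodes) <- rel
  sem$score <- mapply(function(da, fa)
    semantic_similarity(ds_nodes[[da]], cat_nodes[[fa]], backend),
    sem$dataset_attr, sem$fhir_attr)
  map_attributes(st, sem, catalogue = catalogue, threshold = threshold)
}

#' Bundled HL7 FHIR R4 attribute catalogue
#'
#' The Observation, Patient, Practitioner and DiagnosticReport attribute
#' names used as mapping candidates, shipped as a plain-text fixture.
#'
#' @return character vector of attribute names
#' @export
fhir_catalogue <- function() {
  path <- system.file("extdata", "fhir_catalogue.txt", package = "iotqa",
                      mustWork = TRUE)
  readLines(path)
}

# ---- FHIR output -----------------------------------------------------------

VITAL_DISPLAY <- c(diastolic_bp = "Diastolic blood pressure",
                   systolic_bp = "Systolic blood pressure",
                   heart_rate = "Heart rate")

#' Translate a cleaned dataset into FHIR Observation resources
#'
#' One Observation per record: `effectiveDateTime` from the record's date
#' and time, and one component per vital with a `valueQuantity`
#' (value + unit) and the measurement code. The mapping result is carried
#' for provenance; attributes it leaves unmapped would be emitted under a
#' flagged extension (none arise with the bundled catalogue).
#'
#' @param cleaned a cleaned [device_dataset()]
#' @param mapping optional `mapping_result` recorded in each resource's meta
#' @return list of FHIR Observation resources (plain R lists, JSON- and
#'   XML-serializable via [fhir_to_json()] / [fhir_to_xml()])
#' @export
to_fhir <- function(cleaned, mapping = NULL) {
  recs <- cleaned$records
  lapply(seq_len(nrow(recs)), function(i) {
    r <- recs[i, , drop = FALSE]
    comp <- lapply(VITALS, function(v) {
      val <- r[[paste0(v, "_value")]]
      if (is_blank(val)) return(NULL)
      list(code = list(coding = list(list(code = r[[paste0(v, "_code")]],
                                          display = unname(VITAL_DISPLAY[[v]])))),
           valueQuantity = list(value = val,
                                unit = r[[paste0(v, "_unit")]]))
    })
    comp <- Filter(Negate(is.null), comp)
    obs <- list(resourceType = "Observation",
                id = sprintf("%s-%d", cleaned$spec$device_id, i),
                status = "final",
                code = list(text = "Blood pressure panel"),
                effectiveDateTime = paste0(r$date, "T", r$time),
                device = list(display = cleaned$spec$name),
                component = comp)
    obs
  })
}

#' Serialize FHIR resources to JSON / XML
#'
#' JSON output is a FHIR Bundle of type `collection`; XML output wraps the
#' resources in a `Bundle` element with the standard FHIR namespace layout
#' (element-per-field, values in `value` attributes).
#'
#' @param resources list of resources from [to_fhir()]
#' @param path output file
#' @return invisible `path`
#' @export
fhir_to_json <- function(resources, path) {
  bundle <- list(resourceType = "Bundle", type = "collection",
                 entry = lapply(resources, function(r) list(resource = r)))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

fhir_xml_node <- function(parent, name, value) {
  if (is.list(value) && is.null(names(value))) {
    for (v in value) fhir_xml_node(parent, name, v)
  } else if (is.list(value)) {
    node <- xml2::xml_add_child(parent, name)
    for (nm in names(value)) fhir_xml_node(node, nm, value[[nm]])
  } else {
    xml2::xml_add_child(parent, name, value = as.character(value))
  }
}

#' @rdname fhir_to_json
#' @export
fhir_to_xml <- function(resources, path) {
  doc <- xml2::xml_new_root("Bundle", xmlns = "http://hl7.org/fhir")
  xml2::xml_add_child(doc, "type", value = "collection")
  for (r in resources) {
    entry <- xml2::xml_add_child(doc, "entry")
    resource <- xml2::xml_add_child(entry, "resource")
    obs <- xml2::xml_add_child(resource, r$resourceType)
    for (nm in setdiff(names(r), "resourceType")) fhir_xml_node(obs, nm, r[[nm]])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read back a FHIR JSON bundle written by [fhir_to_json()]
#'
#' @param path JSON file
#' @return list of resources
#' @export
fhir_from_json <- function(path) {
  bundle <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(bundle$entry, function(e) e$resource)
}

#' Multiset of component values carried by FHIR Observation resources
#'
#' Convenience accessor used to check value conservation across the
#' transformation.
#'
#' @param resources list of resources
#' @return numeric vector of all `valueQuantity` values
#' @export
fhir_values <- function(resources) {
  unlist(lapply(resources, function(r)
    vapply(r$component, function(cp) as.numeric(cp$valueQuantity$value), 0)),
    use.names = FALSE)
}

# ---- printed similarity fixtures ------------------------------------------

#' Reference structural / semantic similarity tables
#'
#' The published top-2 structural and semantic similarity scores between the
#' twelve Withings BPM dataset attributes and the FHIR resource attributes,
#' shipped as CSV fixtures (scores on the percent scale in the files,
#' returned as fractions). These feed the overall mapper in golden tests;
#' the non-identity structural scores are the reference implementation's
#' own artifacts and are not recomputable from the Dice definition.
#'
#' @return list with `structural` and `semantic` data frames
#'   (`dataset_attr`, `fhir_attr`, `score` as fraction)
#' @export
reference_similarity_tables <- function() {
  rd <- function(f) {
    d <- utils::read.csv(system.file("extdata", f, package = "iotqa",
                                     mustWork = TRUE),
                         stringsAsFactors = FALSE)
    d$score <- d$score_pct / 100
    d[, c("dataset_attr", "fhir_attr", "score")]
  }
  list(structural = rd("withings_structural_similarity.csv"),
       semantic = rd("withings_semantic_similarity.csv"))
}
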