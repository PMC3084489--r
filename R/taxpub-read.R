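#' Parse a TaxPub-style article into the domain model
#'
#' Reads one journal article marked up in the pinned TaxPub/NLM-style
#' element subset (see the schema shipped in
#' `inst/extdata/taxpub-subset.xsd`) and fragments it into bibliographic
#' metadata plus an ordered list of taxon treatments, each with its typed
#' sections, references, figures and identification keys.
#'
#' Unknown elements inside a treatment section are never dropped silently:
#' they are flattened to paragraph text and a warning is raised.
#'
#' @param x path to an XML file, an XML string, or an `xml_document`.
#' @return A [taxpub_article()].
#' @examples
#' fx <- generate_article(seed = 1, n_treatments = 2)
#' art <- parse_article(fx$xml)
#' length(art$treatments)
#' @export
parse_article <- function(x) {
  doc <- read_xml_checked(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "article") {
    abort_parse(sprintf("expected <article> root element, found <%s>",
                        xml2::xml_name(root)))
  }
  meta <- parse_article_meta(root)
  nodes <- xml2::xml_find_all(root, "./body/taxon-treatment")
  treatments <- lapply(nodes, parse_treatment)
  taxpub_article(meta, treatments)
}

read_xml_checked <- function(x) {
  if (inherits(x, "xml_document")) return(x)
  tryCatch(
    xml2::read_xml(x, encoding = "UTF-8"),
    error = function(e) abort_parse(paste0("malformed XML: ", conditionMessage(e)))
  )
}

xtext <- function(node, xpath) {
  found <- xml2::xml_find_first(node, xpath)
  if (inherits(found, "xml_missing")) return(NULL)
  enc_nfc(trimws(xml2::xml_text(found)))
}

parse_article_meta <- function(root) {
  am <- xml2::xml_find_first(root, "./front/article-meta")
  contribs <- xml2::xml_find_all(root, "./front/article-meta/contrib-group/contrib")
  authors <- data.frame(
    surname = vapply(contribs, function(n) xtext(n, "./surname") %||% "", character(1)),
    given = vapply(contribs, function(n) xtext(n, "./given-names") %||% "", character(1)),
    stringsAsFactors = FALSE
  )
  authors <- authors[nzchar(authors$surname), , drop = FALSE]
  year <- xtext(root, "./front/article-meta/pub-date/year")
  month <- xtext(root, "./front/article-meta/pub-date/month")
  day <- xtext(root, "./front/article-meta/pub-date/day")
  pub_date <- NULL
  if (!is.null(year) && !is.null(month) && !is.null(day)) {
    pub_date <- as.Date(sprintf("%s-%02d-%02d", year,
                                as.integer(month), as.integer(day)))
  }
  fpage <- xtext(root, "./front/article-meta/fpage")
  lpage <- xtext(root, "./front/article-meta/lpage")
  pages <- paste(c(fpage, lpage), collapse = "-")

  # Collect everything first so one validation error can list all gaps.
  title <- xtext(root, "./front/article-meta/title-group/article-title")
  journal <- xtext(root, "./front/journal-meta/journal-title")
  missing_fields <- character()
  if (nrow(authors) == 0L) missing_fields <- c(missing_fields, "authors")
  if (is.null(year)) missing_fields <- c(missing_fields, "year")
  if (is.null(title) || !nzchar(title)) missing_fields <- c(missing_fields, "title")
  if (is.null(journal) || !nzchar(journal)) missing_fields <- c(missing_fields, "journal")
  if (length(missing_fields) > 0L) {
    abort_validation(
      paste0("article is missing mandatory bibliographic field(s): ",
             paste(missing_fields, collapse = ", ")),
      fields = missing_fields
    )
  }
  article_meta(
    authors = authors, year = as.integer(year), title = title,
    journal = journal,
    issue_no = xtext(root, "./front/article-meta/issue") %||% "",
    pages = pages,
    doi = xtext(root, "./front/article-meta/article-id[@pub-id-type='doi']"),
    publication_date = pub_date
  )
}

parse_treatment <- function(node) {
  nom <- xml2::xml_find_first(node, "./nomenclature")
  taxon <- parse_taxon_name(xml2::xml_find_first(nom, "./taxon-name"),
                            authorship = xtext(nom, "./taxon-authority") %||% "")
  ranks <- xml2::xml_find_all(nom, "./classification/rank")
  classification <- stats::setNames(
    vapply(ranks, function(n) enc_nfc(trimws(xml2::xml_text(n))), character(1)),
    vapply(ranks, function(n) xml2::xml_attr(n, "name"), character(1))
  )
  sections <- lapply(xml2::xml_find_all(node, "./treatment-sec"), parse_section)
  refs <- vapply(xml2::xml_find_all(node, "./ref-list/ref"),
                 function(n) enc_nfc(trimws(xml2::xml_text(n))), character(1))
  figures <- lapply(xml2::xml_find_all(node, "./fig"), function(n) {
    list(id = xml2::xml_attr(n, "id"),
         caption = xtext(n, "./caption") %||% "",
         filename = xml2::xml_attr(xml2::xml_find_first(n, "./graphic"), "href"))
  })
  keys <- lapply(xml2::xml_find_all(node, "./key"), parse_key)
  treatment(
    taxon = taxon, sections = sections, references = refs,
    figures = figures, keys = keys,
    zoobank_lsid = xtext(nom, "./object-id[@id-type='zoobank']"),
    classification = classification
  )
}

parse_taxon_name <- function(node, authorship = "") {
  part <- function(type) {
    xtext(node, sprintf("./taxon-name-part[@part-type='%s']", type))
  }
  genus <- part("genus")
  if (is.null(genus)) {
    abort_validation("taxon-name without a genus part")
  }
  taxon_name(genus = genus, species_epithet = part("species"),
             infraspecific_epithet = part("subspecies"),
             authorship = authorship)
}

parse_section <- function(node) {
  label <- xml2::xml_attr(node, "sec-title")
  if (is.na(label) || !nzchar(label)) {
    abort_validation("treatment-sec without a sec-title attribute")
  }
  blocks <- lapply(xml2::xml_children(node), function(child) {
    nm <- xml2::xml_name(child)
    if (nm == "p") {
      list(type = "paragraph", text = enc_nfc(trimws(xml2::xml_text(child))))
    } else if (nm == "coordinates") {
      list(type = "coordinate",
           latitude = as.numeric(xml2::xml_attr(child, "latitude")),
           longitude = as.numeric(xml2::xml_attr(child, "longitude")),
           text = enc_nfc(trimws(xml2::xml_text(child))))
    } else if (nm == "ext-link") {
      list(type = "external_id",
           href = xml2::xml_attr(child, "href"),
           label = enc_nfc(trimws(xml2::xml_text(child))))
    } else if (nm == "fig-ref") {
      list(type = "figure_ref", rid = xml2::xml_attr(child, "rid"))
    } else {
      # Legacy documents vary; lossy-but-logged beats brittle.
      tp2w_warn(sprintf(
        "unknown element <%s> in section '%s' flattened to paragraph text",
        nm, label), class = "tp2w_unknown_element")
      list(type = "paragraph", text = enc_nfc(trimws(xml2::xml_text(child))))
    }
  })
  treatment_section(label = label, blocks = blocks)
}

parse_key <- function(node) {
  couplets <- lapply(xml2::xml_find_all(node, "./couplet"), function(cp) {
    leads <- lapply(xml2::xml_find_all(cp, "./lead"), function(ld) {
      out <- list(text = xtext(ld, "./statement") %||% "")
      nxt <- xtext(ld, "./next")
      tax <- xtext(ld, "./taxon")
      if (!is.null(nxt)) out$next_couplet <- as.integer(nxt)
      if (!is.null(tax)) out$taxon <- tax
      out
    })
    list(number = as.integer(xml2::xml_attr(cp, "number")), leads = leads)
  })
  identification_key(couplets)
}

#' Extract one taxon name per treatment, in document order
#'
#' @param article a [taxpub_article()].
#' @return List of [taxon_name()] objects (duplicates allowed).
#' @export
extract_treatment_names <- function(article) {
  if (!inherits(article, "taxpub_article")) {
    abort_validation("extract_treatment_names expects a taxpub_article")
  }
  lapply(article$treatments, function(tr) tr$taxon)
}

#' Validate a document against the pinned TaxPub subset schema
#'
#' @param x path, XML string or `xml_document`.
#' @return `TRUE` invisibly; errors if invalid.
#' @export
validate_taxpub <- function(x) {
  doc <- read_xml_checked(x)
  xsd_path <- system.file("extdata", "taxpub-subset.xsd", package = "taxpub2wiki")
  schema <- xml2::read_xml(xsd_path)
  ok <- xml2::xml_validate(doc, schema)
  if (!ok) {
    abort_validation(paste0("document does not validate against the TaxPub subset schema: ",
                            paste(attr(ok, "errors"), collapse = "; ")))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
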