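#' Domain model for parsed taxonomic articles
#'
#' Lightweight S3 records mirroring the structure of a TaxPub-style journal
#' article: bibliographic metadata, taxon names, treatment sections,
#' identification keys, figures and references. Constructors validate their
#' invariants eagerly so downstream emitters can assume well-formed input.
#'
#' @name taxpub-model
NULL

#' Article bibliographic metadata
#'
#' @param authors data frame with columns `surname` and `given` (initials),
#'   one row per author, in byline order.
#' @param year integer publication year.
#' @param title article title.
#' @param journal journal name.
#' @param issue_no issue number as text.
#' @param pages page range as text (e.g. `"1-12"`).
#' @param doi DOI string starting `"10."`, or `NULL`.
#' @param publication_date `Date` of publication.
#' @return An object of class `article_meta`.
#' @export
article_meta <- function(authors, year, title, journal,
                         issue_no = "", pages = "", doi = NULL,
                         publication_date = NULL) {
  missing_fields <- character()
  if (!is.data.frame(authors) || nrow(authors) == 0L) {
    missing_fields <- c(missing_fields, "authors")
  }
  if (is.null(year) || is.na(suppressWarnings(as.integer(year)))) {
    missing_fields <- c(missing_fields, "year")
  }
  if (is.null(title) || !nzchar(trimws(title))) missing_fields <- c(missing_fields, "title")
  if (is.null(journal) || !nzchar(trimws(journal))) missing_fields <- c(missing_fields, "journal")
  if (length(missing_fields) > 0L) {
    abort_validation(
      paste0("article metadata is missing mandatory field(s): ",
             paste(missing_fields, collapse = ", ")),
      fields = missing_fields
    )
  }
  year <- as.integer(year)
  if (year < 1750L || year > as.integer(format(Sys.Date(), "%Y"))) {
    abort_validation(sprintf("publication year %d outside plausible range [1750, current]", year))
  }
  if (!is.null(doi) && !startsWith(doi, "10.")) {
    abort_validation(sprintf("DOI '%s' does not begin with '10.'", doi))
  }
  structure(
    list(authors = authors, year = year,
         title = enc_nfc(title), journal = enc_nfc(journal),
         issue_no = as.character(issue_no), pages = as.character(pages),
         doi = doi,
         publication_date = if (is.null(publication_date)) NULL else as.Date(publication_date)),
    class = "article_meta"
  )
}

#' Scientific taxon name
#'
#' Rank is derived from which epithets are present; genus is forced to
#' initial capital, epithets to lowercase (Unicode NFC throughout).
#'
#' @param genus genus name.
#' @param species_epithet species epithet, or `NULL` for a genus-rank name.
#' @param infraspecific_epithet subspecific epithet, or `NULL`.
#' @param authorship authorship string, e.g. `"Stoev & Enghoff, 2011"`.
#' @return An object of class `taxon_name`.
#' @export
taxon_name <- function(genus, species_epithet = NULL,
                       infraspecific_epithet = NULL, authorship = "") {
  if (is.null(genus) || !nzchar(trimws(genus))) {
    abort_validation("taxon name requires a non-empty genus")
  }
  if (!is.null(infraspecific_epithet) && is.null(species_epithet)) {
    abort_validation("infraspecific epithet requires a species epithet")
  }
  cap <- function(x) paste0(toupper(substr(x, 1, 1)), substring(x, 2))
  genus <- cap(tolower(enc_nfc(trimws(genus))))
  norm_ep <- function(x) if (is.null(x)) NULL else tolower(enc_nfc(trimws(x)))
  species_epithet <- norm_ep(species_epithet)
  infraspecific_epithet <- norm_ep(infraspecific_epithet)
  rank <- if (!is.null(infraspecific_epithet)) "subspecies"
          else if (!is.null(species_epithet)) "species" else "genus"
  structure(
    list(genus = genus, species_epithet = species_epithet,
         infraspecific_epithet = infraspecific_epithet,
         authorship = enc_nfc(authorship), rank = rank),
    class = "taxon_name"
  )
}

#' @export
format.taxon_name <- function(x, ...) {
  paste(c(x$genus, x$species_epithet, x$infraspecific_epithet), collapse = " ")
}

#' @export
print.taxon_name <- function(x, ...) {
  cat("<taxon_name>", format(x),
      if (nzchar(x$authorship)) x$authorship else NULL, "\n")
  invisible(x)
}

#' One labelled section of a taxon treatment
#'
#' @param label section label (e.g. `"Description"`, `"Distribution"`).
#' @param blocks ordered list of content blocks; each block is a list with a
#'   `type` field in `paragraph`, `figure_ref`, `coordinate`, `external_id`.
#' @return An object of class `treatment_section`.
#' @export
treatment_section <- function(label, blocks = list()) {
  if (is.null(label) || !nzchar(trimws(label))) {
    abort_validation("treatment section label must be non-empty")
  }
  known <- c("paragraph", "figure_ref", "coordinate", "external_id")
  for (b in blocks) {
    if (is.null(b$type) || !b$type %in% known) {
      abort_validation(sprintf("unknown block type '%s'", as.character(b$type)))
    }
  }
  structure(list(label = enc_nfc(label), blocks = blocks),
            class = "treatment_section")
}

#' Dichotomous identification key
#'
#' A key is an ordered list of numbered couplets; each couplet holds leads
#' whose outcome either routes to another couplet or terminates at a taxon.
#'
#' @param couplets list of couplets; each couplet is a list with `number`
#'   (integer) and `leads` (list of lists with `text` and either
#'   `next_couplet` or `taxon`).
#' @return An object of class `identification_key`.
#' @export
identification_key <- function(couplets) {
  numbers <- vapply(couplets, function(cp) as.integer(cp$number), integer(1))
  if (anyDuplicated(numbers)) {
    abort_validation("couplet numbers must be unique within a key")
  }
  any_taxon <- FALSE
  for (cp in couplets) {
    for (ld in cp$leads) {
      has_next <- !is.null(ld$next_couplet)
      has_taxon <- !is.null(ld$taxon)
      if (has_next == has_taxon) {
        abort_validation(sprintf(
          "lead in couplet %d must have exactly one outcome (next couplet or taxon)",
          cp$number))
      }
      if (has_next && !as.integer(ld$next_couplet) %in% numbers) {
        abort_validation(sprintf(
          "couplet %d refers to missing couplet %d",
          cp$number, as.integer(ld$next_couplet)))
      }
      if (has_taxon) any_taxon <- TRUE
    }
  }
  if (!any_taxon) {
    abort_validation("key has no lead resolving to a taxon")
  }
  structure(list(couplets = couplets), class = "identification_key")
}

#' One taxon treatment
#'
#' @param taxon a [taxon_name()].
#' @param sections ordered list of [treatment_section()] objects.
#' @param references character vector of formatted reference entries.
#' @param figures list of figures, each a list with `id`, `caption`,
#'   `filename`.
#' @param keys list of [identification_key()] objects.
#' @param zoobank_lsid nomenclatural act LSID, or `NULL`.
#' @param classification named character vector of higher ranks
#'   (e.g. `c(order = "Callipodida", family = "Sinocallipodidae")`).
#' @return An object of class `treatment`.
#' @export
treatment <- function(taxon, sections = list(), references = character(),
                      figures = list(), keys = list(), zoobank_lsid = NULL,
                      classification = character()) {
  if (!inherits(taxon, "taxon_name")) {
    abort_validation("treatment requires a taxon_name")
  }
  structure(
    list(taxon = taxon, zoobank_lsid = zoobank_lsid,
         sections = sections, references = references,
         figures = figures, keys = keys, classification = classification),
    class = "treatment"
  )
}

#' Parsed TaxPub article: metadata plus ordered treatments
#'
#' @param meta an [article_meta()].
#' @param treatments ordered list of [treatment()] objects (may be empty).
#' @return An object of class `taxpub_article`.
#' @export
taxpub_article <- function(meta, treatments = list()) {
  if (!inherits(meta, "article_meta")) {
    abort_validation("taxpub_article requires article_meta")
  }
  structure(list(meta = meta, treatments = treatments),
            class = "taxpub_article")
}

#' @export
print.taxpub_article <- function(x, ...) {
  cat(sprintf("<taxpub_article> %s (%d): %s\n  %d treatment(s)\n",
              paste(x$meta$authors$surname, collapse = ", "),
              x$meta$year, x$meta$title, length(x$treatments)))
  invisible(x)
}

# Unicode NFC normalisation; authorships and names carry diacritics.
enc_nfc <- function(x) {
  if (is.null(x)) return(NULL)
  stringi_ok <- requireNamespace("stringi", quietly = TRUE)
  if (stringi_ok) stringi::stri_trans_nfc(enc2utf8(x)) else enc2utf8(x)
}
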