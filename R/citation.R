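#' Build the joint journal + wiki citation
#'
#' Combines the original journal publication with one numbered,
#' time-stamped revision of the derived wiki page into a single
#' bibliographic reference: journal half from the article metadata, wiki
#' half (date, version number, permanent link, alphabetical contributor
#' list) computed from the page's revision history.
#'
#' @param meta an [article_meta()].
#' @param history a `page_history` (see [parse_export()]).
#' @param rev_id revision id present in `history`, or `"latest"`.
#' @param config site configuration (see [load_config()]).
#' @param exclude_bots drop bot accounts from the contributor list
#'   (default `TRUE`; the journal half already credits the original
#'   authors and the import is bot-performed).
#' @return An object of class `joint_citation` with fields `source`
#'   (the metadata) and `wiki` (date, `rev_id`, `permanent_url`,
#'   `contributors`).
#' @export
build_joint_citation <- function(meta, history, rev_id = "latest",
                                 config = NULL, exclude_bots = TRUE) {
  cfg <- as_config(config)
  if (identical(rev_id, "latest")) {
    rev_id <- max(history$revisions$rev_id)
  }
  rev_id <- as.integer(rev_id)
  contributors <- contributors_at(history, rev_id, exclude_bots = exclude_bots)
  ts <- history$revisions$timestamp[history$revisions$rev_id == rev_id]
  title <- gsub(" ", "_", history$title)
  wiki <- list(
    date = format(as.Date(ts, tz = "UTC"), "%Y-%m-%d"),
    rev_id = rev_id,
    permanent_url = permanent_url(cfg, title, rev_id),
    contributors = contributors
  )
  structure(list(source = meta, wiki = wiki, config = cfg),
            class = "joint_citation")
}

#' Render a joint citation
#'
#' Supported formats: `"text"` (the single-reference scheme with the
#' literal `Versioned wiki page:` marker), `"bibtex"` (an article entry
#' whose `note` field carries the wiki half), `"ris"` (TY/ER framed,
#' wiki half in `N1`), and `"wikitext"` (a cite-template call).
#'
#' @param citation a `joint_citation`.
#' @param format one of `"text"`, `"bibtex"`, `"ris"`, `"wikitext"`.
#' @return A single string.
#' @export
render_citation <- function(citation, format = c("text", "bibtex", "ris", "wikitext")) {
  if (!inherits(citation, "joint_citation")) {
    abort_validation("render_citation expects a joint_citation")
  }
  if (length(format) != 1L || !format %in% c("text", "bibtex", "ris", "wikitext")) {
    format <- tryCatch(match.arg(format),
                       error = function(e) abort_usage(paste0(
                         "unknown citation format: ",
                         paste(format, collapse = ", "))))
  }
  switch(format,
         text = render_text(citation),
         bibtex = render_bibtex(citation),
         ris = render_ris(citation),
         wikitext = render_wikitext(citation))
}

#' @export
print.joint_citation <- function(x, ...) {
  cat(render_text(x), "\n")
  invisible(x)
}

# "Surname Initials" joined by ", " — the journal reference style.
format_authors_text <- function(authors) {
  paste(trimws(paste(authors$surname, authors$given)), collapse = ", ")
}

contributors_token <- function(citation) {
  contributors <- citation$wiki$contributors
  if (length(contributors) == 0L) {
    citation$config$empty_contributors_token %||% "none"
  } else {
    paste(contributors, collapse = ", ")
  }
}

wiki_half_text <- function(citation) {
  sprintf("Versioned wiki page: %s, version %d, %s, contributors (alphabetical order): %s.",
          citation$wiki$date, citation$wiki$rev_id, citation$wiki$permanent_url,
          contributors_token(citation))
}

render_text <- function(citation) {
  m <- citation$source
  journal_half <- sprintf("%s (%d) %s. %s %s: %s.",
                          format_authors_text(m$authors), m$year, m$title,
                          m$journal, m$issue_no, m$pages)
  if (!is.null(m$doi)) {
    journal_half <- paste0(journal_half, " doi:", m$doi, ".")
  }
  paste(journal_half, wiki_half_text(citation))
}

bibtex_escape <- function(x) gsub("([{}])", "\\\\\\1", x)

render_bibtex <- function(citation) {
  m <- citation$source
  key <- sprintf("%s%d_rev%d",
                 gsub("[^A-Za-z]", "", m$authors$surname[1]),
                 m$year, citation$wiki$rev_id)
  authors <- paste(
    trimws(paste0(m$authors$surname, ", ", gsub(" ", ". ", m$authors$given),
                  ifelse(nzchar(m$authors$given), ".", ""))),
    collapse = " and ")
  fields <- c(
    author = authors,
    year = as.character(m$year),
    title = bibtex_escape(m$title),
    journal = bibtex_escape(m$journal),
    volume = m$issue_no,
    pages = gsub("-", "--", m$pages, fixed = TRUE),
    if (!is.null(m$doi)) c(doi = m$doi),
    url = citation$wiki$permanent_url,
    note = bibtex_escape(wiki_half_text(citation))
  )
  fields <- fields[nzchar(fields)]
  lines <- sprintf("  %s = {%s},", names(fields), unname(fields))
  lines[length(lines)] <- sub(",$", "", lines[length(lines)])
  body <- paste(lines, collapse = "\n")
  sprintf("@article{%s,\n%s\n}", key, body)
}

render_ris <- function(citation) {
  m <- citation$source
  pages <- strsplit(m$pages, "-", fixed = TRUE)[[1]]
  lines <- c(
    "TY  - JOUR",
    sprintf("AU  - %s", trimws(paste0(m$authors$surname, ", ", m$authors$given))),
    sprintf("PY  - %d", m$year),
    sprintf("TI  - %s", m$title),
    sprintf("JO  - %s", m$journal),
    if (nzchar(m$issue_no)) sprintf("IS  - %s", m$issue_no),
    if (length(pages) >= 1 && nzchar(pages[1])) sprintf("SP  - %s", pages[1]),
    if (length(pages) >= 2) sprintf("EP  - %s", pages[2]),
    if (!is.null(m$doi)) sprintf("DO  - %s", m$doi),
    sprintf("UR  - %s", citation$wiki$permanent_url),
    sprintf("N1  - %s", wiki_half_text(citation)),
    "ER  - "
  )
  paste(lines, collapse = "\n")
}

render_wikitext <- function(citation) {
  call <- citation_template_call(citation)
  call$name <- citation$config$templates$wikitext_cite %||% "cite journal"
  render_template_call(call)
}

#' Citation template call for a wiki page
#'
#' Produces the template call placed at the top of every exported page.
#' With `placeholder = TRUE` the wiki-side fields (date, revision,
#' contributors) carry MediaWiki magic words so the live template always
#' shows the currently displayed version; otherwise they are the
#' concrete values of the cited revision.
#'
#' @param citation a `joint_citation`.
#' @param placeholder use live magic-word placeholders for the wiki half?
#' @return A [template_call()].
#' @export
citation_template_call <- function(citation, placeholder = FALSE) {
  m <- citation$source
  params <- citation_journal_params(m)
  if (placeholder) {
    params$date <- "{{REVISIONYEAR}}-{{REVISIONMONTH}}-{{REVISIONDAY2}}"
    params$revision <- "{{REVISIONID}}"
    params$url <- "{{fullurl:{{FULLPAGENAME}}|oldid={{REVISIONID}}}}"
    params$contributors <- "{{CONTRIBUTORS}}"
  } else {
    params$date <- citation$wiki$date
    params$revision <- as.character(citation$wiki$rev_id)
    params$url <- citation$wiki$permanent_url
    params$contributors <- contributors_token(citation)
  }
  template_call(citation$config$templates$citation %||% "Cite treatment", params)
}

citation_journal_params <- function(meta) {
  params <- list(
    authors = format_authors_text(meta$authors),
    year = as.character(meta$year),
    title = meta$title,
    journal = meta$journal,
    issue = meta$issue_no,
    pages = meta$pages
  )
  params$doi <- meta$doi %||% ""
  params
}
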