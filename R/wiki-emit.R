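#' Wiki page title for a taxon
#'
#' Joins genus and epithets with underscores, genus capitalised and
#' epithets lowercase, the form used in wiki page URLs
#' (`.../wiki/Sinocallipus_catba`).
#'
#' @param taxon a [taxon_name()].
#' @return Page title string without spaces.
#' @examples
#' page_title(taxon_name("Sinocallipus", "catba"))
#' @export
page_title <- function(taxon) {
  if (!inherits(taxon, "taxon_name")) {
    abort_validation("page_title expects a taxon_name")
  }
  parts <- c(taxon$genus, taxon$species_epithet, taxon$infraspecific_epithet)
  if (any(!nzchar(parts))) {
    abort_validation("taxon name has an empty component")
  }
  paste(parts, collapse = "_")
}

#' Resolve external-resource links for a taxon
#'
#' Substitutes the URL-encoded taxon name (`"Genus species"`,
#' percent-encoded) into each registry entry's URL template, preserving
#' registry order.
#'
#' @param taxon a [taxon_name()].
#' @param registry a [resource_registry()].
#' @return Data frame with columns `resource` and `url`, one row per
#'   registry entry.
#' @export
external_links <- function(taxon, registry) {
  if (!inherits(registry, "resource_registry")) {
    abort_validation("external_links expects a resource_registry")
  }
  name <- format(taxon)
  encoded <- utils::URLencode(name, reserved = TRUE)
  data.frame(
    resource = vapply(registry$entries, function(e) e$name, character(1)),
    url = vapply(registry$entries,
                 function(e) gsub("{name}", encoded, e$url, fixed = TRUE),
                 character(1)),
    stringsAsFactors = FALSE
  )
}

#' Render a dichotomous key as a wiki table
#'
#' One table row per lead: couplet number, lead text, and the outcome —
#' an internal `[[Genus_species]]` link for taxon outcomes or an anchor
#' link to the target couplet row otherwise.
#'
#' @param key an [identification_key()].
#' @return A single wikitext string.
#' @export
emit_key <- function(key) {
  if (!inherits(key, "identification_key")) {
    key <- identification_key(key$couplets %||% key)  # revalidates
  }
  rows <- character()
  for (cp in key$couplets) {
    first <- TRUE
    for (ld in cp$leads) {
      anchor <- if (first) sprintf('<span id="couplet-%d"></span>', cp$number) else ""
      outcome <- if (!is.null(ld$taxon)) {
        sprintf("[[%s]]", gsub(" ", "_", ld$taxon))
      } else {
        sprintf("[[#couplet-%d|%d]]", ld$next_couplet, ld$next_couplet)
      }
      rows <- c(rows, "|-",
                sprintf("| %s%d || %s || %s", anchor, cp$number,
                        wiki_escape(ld$text), outcome))
      first <- FALSE
    }
  }
  paste(c('{| class="wikitable"', "! # !! Lead !! Outcome", rows, "|}"),
        collapse = "\n")
}

#' Convert one treatment into a MediaWiki page
#'
#' The page carries, in order: the citation template (journal half filled
#' from the article metadata, wiki half left as live magic-word
#' parameters so the rendered template self-updates), the taxonomic
#' classification template, one level-2 heading per treatment section in
#' source order, identification keys, figures, the reference list, and
#' the external-links template resolved from the resource registry.
#' ZooBank LSIDs and tagged coordinates are carried over as external
#' links.
#'
#' @param treatment a [treatment()].
#' @param meta the article's [article_meta()].
#' @param registry a [resource_registry()]; default from `config`.
#' @param config site configuration (see [load_config()]).
#' @return An object of class `wiki_page` with fields `title`, `markup`
#'   and `images` (data frame mapping source file to wiki file name).
#' @export
emit_page <- function(treatment, meta, registry = NULL, config = NULL) {
  cfg <- as_config(config)
  if (is.null(registry)) registry <- registry_from_config(cfg)
  title <- page_title(treatment$taxon)

  chunks <- character()

  cite_call <- template_call(
    cfg$templates$citation,
    c(citation_journal_params(meta),
      list(date = "{{REVISIONYEAR}}-{{REVISIONMONTH}}-{{REVISIONDAY2}}",
           revision = "{{REVISIONID}}",
           contributors = "{{CONTRIBUTORS}}"))
  )
  chunks <- c(chunks, render_template_call(cite_call))

  cls <- as.list(treatment$classification)
  cls$genus <- treatment$taxon$genus
  if (!is.null(treatment$taxon$species_epithet)) {
    cls$species <- treatment$taxon$species_epithet
  }
  if (!is.null(treatment$taxon$infraspecific_epithet)) {
    cls$subspecies <- treatment$taxon$infraspecific_epithet
  }
  if (nzchar(treatment$taxon$authorship)) cls$authority <- treatment$taxon$authorship
  if (!is.null(treatment$zoobank_lsid)) {
    cls$zoobank <- paste0("http://zoobank.org/", treatment$zoobank_lsid)
  }
  chunks <- c(chunks,
              render_template_call(template_call(cfg$templates$classification, cls)))

  fig_names <- wiki_image_names(title, treatment$figures)
  for (sec in treatment$sections) {
    chunks <- c(chunks, sprintf("== %s ==", sec$label),
                render_blocks(sec$blocks, treatment$figures, fig_names))
  }

  if (length(treatment$keys) > 0L) {
    chunks <- c(chunks, "== Identification key ==",
                vapply(treatment$keys, emit_key, character(1)))
  }

  if (length(treatment$figures) > 0L) {
    chunks <- c(chunks, "== Figures ==")
    for (i in seq_along(treatment$figures)) {
      fg <- treatment$figures[[i]]
      chunks <- c(chunks, sprintf("[[File:%s|thumb|%s]]",
                                  fig_names[i], wiki_escape(fg$caption)))
    }
  }

  if (length(treatment$references) > 0L) {
    chunks <- c(chunks, "== References ==",
                paste0("* ", vapply(treatment$references, wiki_escape, character(1))))
  }

  links <- external_links(treatment$taxon, registry)
  link_params <- c(list(name = format(treatment$taxon)),
                   stats::setNames(as.list(links$url), links$resource))
  chunks <- c(chunks,
              render_template_call(template_call(cfg$templates$external_links,
                                                 link_params)))

  markup <- paste0(paste(chunks, collapse = "\n\n"), "\n")
  images <- data.frame(
    source = vapply(treatment$figures, function(f) f$filename, character(1)),
    wiki_name = fig_names,
    stringsAsFactors = FALSE
  )
  structure(list(title = title, markup = markup, images = images),
            class = "wiki_page")
}

# "<PageTitle>_fig<N>.<ext>": the source names figure files arbitrarily.
wiki_image_names <- function(title, figures) {
  if (length(figures) == 0L) return(character())
  ext <- vapply(figures, function(f) {
    e <- tools::file_ext(f$filename)
    if (nzchar(e)) e else "png"
  }, character(1))
  sprintf("%s_fig%d.%s", title, seq_along(figures), ext)
}

render_blocks <- function(blocks, figures, fig_names) {
  out <- character()
  fig_ids <- vapply(figures, function(f) f$id %||% "", character(1))
  for (b in blocks) {
    out <- c(out, switch(
      b$type,
      paragraph = wiki_escape(b$text),
      coordinate = sprintf(
        "[http://www.openstreetmap.org/?mlat=%s&mlon=%s %s]",
        b$latitude, b$longitude, wiki_escape(b$text)),
      external_id = sprintf("[%s %s]", b$href, wiki_escape(b$label)),
      figure_ref = {
        idx <- match(b$rid, fig_ids)
        if (is.na(idx)) sprintf("(Fig. %s)", b$rid)
        else sprintf("(see [[:File:%s|Fig. %s]])", fig_names[idx], b$rid)
      }
    ))
  }
  out
}

#' Emit all pages of an article
#'
#' @inheritParams emit_page
#' @param article a [taxpub_article()].
#' @return List of `wiki_page` objects, one per treatment.
#' @export
emit_article <- function(article, registry = NULL, config = NULL) {
  cfg <- as_config(config)
  if (is.null(registry)) registry <- registry_from_config(cfg)
  pages <- lapply(article$treatments, emit_page,
                  meta = article$meta, registry = registry, config = cfg)
  titles <- vapply(pages, function(p) p$title, character(1))
  dup <- titles[duplicated(titles)]
  if (length(dup) > 0L) {
    if (identical(cfg$title_collision, "suffix")) {
      seen <- character()
      for (i in seq_along(pages)) {
        title <- titles[i]
        if (title %in% seen) {
          suffix <- gsub(" ", "_", article$treatments[[i]]$taxon$authorship)
          candidate <- sprintf("%s_(%s)", title, suffix)
          k <- 2L
          while (candidate %in% seen) {
            candidate <- sprintf("%s_(%s)_%d", title, suffix, k)
            k <- k + 1L
          }
          title <- candidate
        }
        pages[[i]]$title <- title
        seen <- c(seen, title)
      }
    } else {
      abort_validation(paste0(
        "treatments map onto the same page title(s): ",
        paste(unique(dup), collapse = ", "),
        "; set title_collision: suffix to disambiguate"))
    }
  }
  pages
}

# --- wikitext primitives ----------------------------------------------------

#' Construct a wiki template call
#'
#' @param name template name.
#' @param params named list of parameter values (order preserved; keys
#'   must be unique).
#' @return An object of class `template_call`.
#' @export
template_call <- function(name, params = list()) {
  keys <- names(params)
  if (anyDuplicated(keys)) {
    abort_validation("template parameter keys must be unique within one call")
  }
  structure(list(name = name, params = params), class = "template_call")
}

#' @rdname template_call
#' @param call a `template_call`.
#' @export
render_template_call <- function(call) {
  if (length(call$params) == 0L) return(sprintf("{{%s}}", call$name))
  lines <- vapply(names(call$params), function(k) {
    sprintf("| %s = %s", k, as.character(call$params[[k]]))
  }, character(1))
  paste(c(sprintf("{{%s", call$name), lines, "}}"), collapse = "\n")
}

#' Escape wiki-special characters in free text
#'
#' Pipes and paired braces/brackets inside content would otherwise break
#' the surrounding templates and tables; they are wrapped in
#' `<nowiki>` spans.
#'
#' @param text character scalar.
#' @return Escaped text.
#' @export
wiki_escape <- function(text) {
  if (is.null(text) || !nzchar(text)) return("")
  gsub("(\\{\\{|\\}\\}|\\[\\[|\\]\\]|\\|)", "<nowiki>\\1</nowiki>", text)
}

#' Check wikitext for unbalanced templates and links
#'
#' Scans the markup (ignoring `<nowiki>` spans) and verifies that every
#' `{{` has a matching `}}` and every `[[` a matching `]]`.
#'
#' @param markup wikitext string.
#' @return `TRUE` if balanced, otherwise `FALSE` with attribute
#'   `errors` describing the imbalance.
#' @export
wiki_check_markup <- function(markup) {
  stripped <- gsub("<nowiki>.*?</nowiki>", "", markup)
  count <- function(pat) {
    sum(lengths(regmatches(stripped, gregexpr(pat, stripped, fixed = TRUE))))
  }
  errors <- character()
  if (count("{{") != count("}}")) {
    errors <- c(errors, sprintf("unbalanced templates: %d '{{' vs %d '}}'",
                                count("{{"), count("}}")))
  }
  if (count("[[") != count("]]")) {
    errors <- c(errors, sprintf("unbalanced links: %d '[[' vs %d ']]'",
                                count("[["), count("]]")))
  }
  if (length(errors) > 0L) return(structure(FALSE, errors = errors))
  TRUE
}
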