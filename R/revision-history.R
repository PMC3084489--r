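#' Parse a MediaWiki XML export dump
#'
#' Reads the standard `<mediawiki><page><revision>` export format and
#' returns one page history per `<page>`, revisions sorted ascending by
#' their site-wide revision id. Revision ids are consecutive across all
#' pages of one wiki, so a single page's ids are usually non-consecutive.
#'
#' MediaWiki dumps carry no explicit bot flag; accounts whose username
#' matches the configured `bot_pattern` (default `"[Bb]ot[0-9]*$"`) are
#' marked as bots. Anonymous edits are attributed to their IP string.
#'
#' @param x path to a dump file, an XML string, or an `xml_document`.
#' @param config site configuration (see [load_config()]); supplies
#'   `bot_pattern`.
#' @return List of `page_history` objects, each with fields `title` and
#'   `revisions` (data frame: `rev_id`, `timestamp`, `user`, `is_bot`,
#'   `comment`, `text`).
#' @export
parse_export <- function(x, config = NULL) {
  cfg <- as_config(config)
  doc <- read_xml_checked(x)
  doc_nons <- doc
  xml2::xml_ns_strip(doc_nons)
  root <- xml2::xml_root(doc_nons)
  if (xml2::xml_name(root) != "mediawiki") {
    abort_parse(sprintf("expected <mediawiki> root element, found <%s>",
                        xml2::xml_name(root)))
  }
  pages <- xml2::xml_find_all(root, "./page")
  histories <- lapply(pages, parse_page_history, bot_pattern = cfg$bot_pattern)
  all_ids <- unlist(lapply(histories, function(h) h$revisions$rev_id))
  if (anyDuplicated(all_ids)) {
    abort_validation("revision ids are not unique across the dump")
  }
  histories
}

parse_page_history <- function(page_node, bot_pattern) {
  title <- xtext(page_node, "./title")
  revs <- xml2::xml_find_all(page_node, "./revision")
  if (length(revs) == 0L) {
    abort_validation(sprintf("page '%s' has no revisions", title))
  }
  rev_id <- vapply(revs, function(r) as.integer(xml2::xml_text(
    xml2::xml_find_first(r, "./id"))), integer(1))
  timestamp <- as.POSIXct(
    vapply(revs, function(r) xml2::xml_text(xml2::xml_find_first(r, "./timestamp")),
           character(1)),
    format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  user <- vapply(revs, function(r) {
    u <- xtext(r, "./contributor/username")
    if (is.null(u)) u <- xtext(r, "./contributor/ip")
    u %||% ""
  }, character(1))
  comment <- vapply(revs, function(r) xtext(r, "./comment") %||% "", character(1))
  text <- vapply(revs, function(r) xtext(r, "./text") %||% "", character(1))
  rv <- data.frame(rev_id = rev_id, timestamp = timestamp, user = user,
                   is_bot = grepl(bot_pattern, user), comment = comment,
                   text = text, stringsAsFactors = FALSE)
  if (is.unsorted(rv$rev_id, strictly = TRUE)) {
    tp2w_warn(sprintf("revisions of page '%s' out of order in dump; reordered", title),
              class = "tp2w_reordered_revisions")
    rv <- rv[order(rv$rev_id), , drop = FALSE]
    rownames(rv) <- NULL
  }
  page_history(title, rv)
}

#' @rdname parse_export
#' @param title page title.
#' @param revisions revision data frame (see above), ascending `rev_id`.
#' @export
page_history <- function(title, revisions) {
  if (nrow(revisions) == 0L) {
    abort_validation("page history must contain at least one revision")
  }
  if (is.unsorted(revisions$rev_id, strictly = TRUE)) {
    abort_validation("revisions must be strictly ascending by rev_id")
  }
  if (is.unsorted(revisions$timestamp)) {
    abort_validation("timestamps must be non-decreasing with rev_id")
  }
  structure(list(title = title, revisions = revisions), class = "page_history")
}

#' @export
print.page_history <- function(x, ...) {
  cat(sprintf("<page_history> %s: %d revision(s), rev_id %d..%d\n",
              x$title, nrow(x$revisions),
              min(x$revisions$rev_id), max(x$revisions$rev_id)))
  invisible(x)
}

#' Contributors to a page up to a given revision
#'
#' Returns the deduplicated usernames of everyone who edited the page in
#' any revision up to and including `rev_id`, sorted alphabetically
#' (case-insensitive, with a case-sensitive tiebreak, in the C locale so
#' the order is reproducible across systems). Bot accounts are excluded
#' by default: the import bot's journal authors are already credited in
#' the journal half of a joint citation.
#'
#' @param history a `page_history`.
#' @param rev_id revision id; must be present in this page's history.
#' @param exclude_bots drop accounts flagged as bots?
#' @return Character vector of usernames (possibly empty).
#' @export
contributors_at <- function(history, rev_id, exclude_bots = TRUE) {
  rv <- history$revisions
  rev_id <- as.integer(rev_id)
  if (!rev_id %in% rv$rev_id) {
    abort_lookup(sprintf("revision %d not found in history of page '%s'",
                         rev_id, history$title))
  }
  rv <- rv[rv$rev_id <= rev_id, , drop = FALSE]
  if (isTRUE(exclude_bots)) rv <- rv[!rv$is_bot, , drop = FALSE]
  users <- unique(rv$user)
  users[order(tolower(users), users, method = "radix")]
}

#' Generic and permanent wiki URLs
#'
#' The generic link always resolves to the newest version of a page; a
#' permanent link pins one numbered revision via the `oldid` query
#' parameter.
#'
#' @param config site configuration supplying `site$base_url` and
#'   `site$script_path`.
#' @param title wiki page title (underscored form).
#' @param rev_id revision number for the permanent link.
#' @return URL string.
#' @examples
#' generic_url(NULL, "Sinocallipus_catba")
#' permanent_url(NULL, "Sinocallipus_catba", 12345)
#' @export
generic_url <- function(config, title) {
  cfg <- as_config(config)
  paste0(cfg$site$base_url, "/wiki/", title)
}

#' @rdname generic_url
#' @export
permanent_url <- function(config, title, rev_id) {
  cfg <- as_config(config)
  paste0(cfg$site$base_url, cfg$site$script_path,
         "/index.php?title=", title, "&oldid=", as.integer(rev_id))
}
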