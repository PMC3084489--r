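#' Deterministic synthetic fixtures
#'
#' Generators for the two input formats the pipeline consumes — TaxPub
#' subset articles and MediaWiki export dumps — together with
#' machine-readable ground-truth manifests, so every reader and emitter
#' is testable offline. A single integer seed drives a dedicated
#' pseudo-random stream per generator (the two generators never share a
#' stream, so extending one cannot perturb the other), and regeneration
#' with the same seed is byte-identical.
#'
#' @name fixtures
NULL

# Run fn under an isolated RNG stream, restoring global RNG state.
with_fixture_rng <- function(seed, stream_offset, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + stream_offset) %% .Machine$integer.max)
  fn()
}

# Pronounceable pseudo-Latin word: alternating consonant/vowel clusters.
rword <- function(n_syllables = 2) {
  consonants <- c("b", "c", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r",
                  "s", "t", "v", "z", "ch", "th", "st", "ph", "br", "cr",
                  "dr", "pl", "tr")
  vowels <- c("a", "e", "i", "o", "u", "ae", "ia", "io", "eo")
  paste0(paste0(sample(consonants, n_syllables, replace = TRUE),
                sample(vowels, n_syllables, replace = TRUE)),
         collapse = "")
}

rcap <- function(x) paste0(toupper(substr(x, 1, 1)), substring(x, 2))

rgenus <- function() rcap(paste0(rword(sample(2:3, 1)),
                                 sample(c("us", "a", "um", "is", "ops"), 1)))
repithet <- function() paste0(rword(sample(2:3, 1)),
                              sample(c("i", "ae", "ensis", "icus", "ella", "atus"), 1))
rsurname <- function() rcap(rword(sample(2:3, 1)))

runique <- function(n, gen) {
  out <- character(0)
  while (length(out) < n) out <- unique(c(out, gen()))
  out[seq_len(n)]
}

SECTION_POOL <- c("Type locality", "Description", "Distribution", "Etymology",
                  "Diagnosis", "Ecology", "Materials examined", "Remarks")

#' Generate a synthetic TaxPub article
#'
#' Emulates an XML-first taxonomic journal article: bibliographic
#' metadata plus `n_treatments` taxon treatments, each with labelled
#' sections, references, figure stubs and (for every third treatment) a
#' small dichotomous key. Taxon names come from a pronounceable
#' generator and are unique within the article. The output validates
#' against the shipped TaxPub subset schema.
#'
#' @param seed integer seed; same seed, byte-identical XML.
#' @param n_treatments number of treatments (may be 0).
#' @param sections_per_treatment number of sections per treatment
#'   (drawn, in order, from a fixed label pool of 8).
#' @return List with `xml` (a single XML string) and `manifest`
#'   (ground truth: metadata, per-treatment taxon names, section labels,
#'   figure/reference counts, key shape).
#' @export
generate_article <- function(seed = 1, n_treatments = 3,
                             sections_per_treatment = 4) {
  stopifnot(n_treatments >= 0, sections_per_treatment >= 0,
            sections_per_treatment <= length(SECTION_POOL))
  with_fixture_rng(seed, 0L, function() {
    n_authors <- sample(2:4, 1)
    authors <- data.frame(
      surname = runique(n_authors, rsurname),
      given = vapply(seq_len(n_authors), function(i)
        paste(sample(LETTERS, sample(1:2, 1)), collapse = " "), character(1)),
      stringsAsFactors = FALSE
    )
    year <- sample(2009:2011, 1)
    fpage <- sample(1:50, 1)
    meta <- list(
      authors = authors,
      year = year,
      title = sprintf("New and poorly known species of %s from synthetic localities",
                      rgenus()),
      journal = sample(c("ZooKeys", "PhytoKeys"), 1),
      issue_no = as.character(sample(10:120, 1)),
      pages = sprintf("%d-%d", fpage, fpage + sample(5:40, 1)),
      doi = sprintf("10.9999/synthetic.%d.%d", sample(10:120, 1), sample(1000:9999, 1)),
      publication_date = sprintf("%d-%02d-%02d", year, sample(1:12, 1), sample(1:28, 1))
    )

    genera <- runique(max(1L, ceiling(n_treatments / 2)), rgenus)
    epithets <- runique(max(1L, n_treatments), repithet)
    treatments <- lapply(seq_len(n_treatments), function(i) {
      genus <- genera[((i - 1L) %% length(genera)) + 1L]
      auth_surname <- authors$surname[sample(nrow(authors), 1)]
      labels <- SECTION_POOL[sort(sample(length(SECTION_POOL),
                                         sections_per_treatment))]
      n_figures <- sample(0:2, 1)
      n_references <- sample(1:3, 1)
      has_key <- (i %% 3L == 0L)
      key_shape <- if (has_key) {
        n_couplets <- 3L
        list(n_couplets = n_couplets, n_leads = 2L * n_couplets)
      } else NULL
      list(
        genus = genus,
        species_epithet = epithets[i],
        authorship = sprintf("%s, %d", auth_surname, year),
        zoobank_lsid = sprintf("urn:lsid:zoobank.org:act:%08X", sample.int(2^25, 1)),
        classification = list(order = rcap(paste0(rword(2), "ida")),
                              family = rcap(paste0(rword(2), "idae"))),
        section_labels = labels,
        n_figures = n_figures,
        n_references = n_references,
        key_shape = key_shape
      )
    })
    manifest <- list(seed = as.integer(seed), meta = meta, treatments = treatments)
    list(xml = build_article_xml(manifest), manifest = manifest)
  })
}

build_article_xml <- function(manifest) {
  m <- manifest$meta
  doc <- xml2::xml_new_root("article", "dtd-version" = "tp-subset-1.0")
  front <- xml2::xml_add_child(doc, "front")
  jm <- xml2::xml_add_child(front, "journal-meta")
  xml2::xml_add_child(jm, "journal-title", m$journal)
  am <- xml2::xml_add_child(front, "article-meta")
  tg <- xml2::xml_add_child(am, "title-group")
  xml2::xml_add_child(tg, "article-title", m$title)
  cg <- xml2::xml_add_child(am, "contrib-group")
  for (i in seq_len(nrow(m$authors))) {
    ct <- xml2::xml_add_child(cg, "contrib")
    xml2::xml_add_child(ct, "surname", m$authors$surname[i])
    xml2::xml_add_child(ct, "given-names", m$authors$given[i])
  }
  pd <- xml2::xml_add_child(am, "pub-date")
  date_parts <- strsplit(m$publication_date, "-")[[1]]
  xml2::xml_add_child(pd, "day", date_parts[3])
  xml2::xml_add_child(pd, "month", date_parts[2])
  xml2::xml_add_child(pd, "year", date_parts[1])
  xml2::xml_add_child(am, "issue", m$issue_no)
  pages <- strsplit(m$pages, "-")[[1]]
  xml2::xml_add_child(am, "fpage", pages[1])
  xml2::xml_add_child(am, "lpage", pages[2])
  xml2::xml_add_child(am, "article-id", m$doi, "pub-id-type" = "doi")

  body <- xml2::xml_add_child(doc, "body")
  all_names <- vapply(manifest$treatments, function(tr)
    paste(tr$genus, tr$species_epithet), character(1))
  for (ti in seq_along(manifest$treatments)) {
    tr <- manifest$treatments[[ti]]
    tn <- xml2::xml_add_child(body, "taxon-treatment")
    nom <- xml2::xml_add_child(tn, "nomenclature")
    txn <- xml2::xml_add_child(nom, "taxon-name")
    xml2::xml_add_child(txn, "taxon-name-part", tr$genus, "part-type" = "genus")
    xml2::xml_add_child(txn, "taxon-name-part", tr$species_epithet,
                        "part-type" = "species")
    xml2::xml_add_child(nom, "taxon-authority", tr$authorship)
    xml2::xml_add_child(nom, "object-id", tr$zoobank_lsid, "id-type" = "zoobank")
    cls <- xml2::xml_add_child(nom, "classification")
    xml2::xml_add_child(cls, "rank", tr$classification$order, "name" = "order")
    xml2::xml_add_child(cls, "rank", tr$classification$family, "name" = "family")

    for (si in seq_along(tr$section_labels)) {
      label <- tr$section_labels[si]
      sec <- xml2::xml_add_child(tn, "treatment-sec", "sec-title" = label)
      xml2::xml_add_child(sec, "p", sprintf(
        "Synthetic %s text for %s %s (paragraph %d).",
        tolower(label), tr$genus, tr$species_epithet, si))
      if (label == "Type locality") {
        lat <- round(-60 + 120 * ((ti * 7 + si * 3) %% 100) / 100, 4)
        lon <- round(-180 + 360 * ((ti * 13 + si * 5) %% 100) / 100, 4)
        xml2::xml_add_child(sec, "coordinates",
                            sprintf("%.4f, %.4f", lat, lon),
                            latitude = sprintf("%.4f", lat),
                            longitude = sprintf("%.4f", lon))
      }
      if (si == 1L && tr$n_figures > 0L) {
        xml2::xml_add_child(sec, "fig-ref", rid = sprintf("F%d-1", ti))
      }
    }
    if (!is.null(tr$key_shape)) {
      key <- xml2::xml_add_child(tn, "key")
      nc <- tr$key_shape$n_couplets
      for (k in seq_len(nc)) {
        cp <- xml2::xml_add_child(key, "couplet", number = as.character(k))
        ld1 <- xml2::xml_add_child(cp, "lead")
        xml2::xml_add_child(ld1, "statement",
                            sprintf("Character state %d-a present", k))
        if (k < nc) {
          xml2::xml_add_child(ld1, "next", as.character(k + 1L))
        } else {
          xml2::xml_add_child(ld1, "taxon", all_names[ti])
        }
        ld2 <- xml2::xml_add_child(cp, "lead")
        xml2::xml_add_child(ld2, "statement",
                            sprintf("Character state %d-b present", k))
        other <- all_names[((ti + k - 1L) %% length(all_names)) + 1L]
        xml2::xml_add_child(ld2, "taxon", other)
      }
    }
    if (tr$n_references > 0L) {
      rl <- xml2::xml_add_child(tn, "ref-list")
      for (r in seq_len(tr$n_references)) {
        xml2::xml_add_child(rl, "ref", sprintf(
          "Synthetic reference %d for %s %s.", r, tr$genus, tr$species_epithet),
          id = sprintf("B%d-%d", ti, r))
      }
    }
    for (f in seq_len(tr$n_figures)) {
      fg <- xml2::xml_add_child(tn, "fig", id = sprintf("F%d-%d", ti, f))
      xml2::xml_add_child(fg, "caption", sprintf(
        "%s %s, synthetic figure %d.", tr$genus, tr$species_epithet, f))
      xml2::xml_add_child(fg, "graphic",
                          href = sprintf("source_image_%d_%d.png", ti, f))
    }
  }
  as.character(doc)
}

#' Generate a synthetic MediaWiki export dump
#'
#' Emulates a wiki hosting imported taxon pages: `n_pages` pages sharing
#' one site-wide, consecutive revision-id sequence (so one page's ids
#' are interleaved with the others'), strictly increasing timestamps,
#' and a user pool in which `round(bot_fraction * n_users)` accounts are
#' bots (named so they match the default bot pattern). The first
#' revision of each page is the automated import and embeds the
#' citation template, so a joint citation is recoverable from the dump
#' alone.
#'
#' @param seed integer seed; same seed, byte-identical XML.
#' @param n_pages number of pages (>= 1).
#' @param n_revisions total revisions across all pages (>= `n_pages`).
#' @param n_users size of the user pool.
#' @param bot_fraction fraction of the user pool that are bot accounts.
#' @return List with `xml` (dump string) and `manifest` (page titles,
#'   per-page revisions with `rev_id`, `user`, `timestamp`, `is_bot`,
#'   and the article metadata embedded in the import revision).
#' @export
generate_history <- function(seed = 1, n_pages = 2, n_revisions = 10,
                             n_users = 5, bot_fraction = 0.2) {
  stopifnot(n_pages >= 1, n_revisions >= n_pages, n_users >= 1,
            bot_fraction >= 0, bot_fraction <= 1)
  with_fixture_rng(seed, 1000003L, function() {
    n_bots <- round(bot_fraction * n_users)
    if (bot_fraction > 0 && n_bots == 0L) n_bots <- 1L
    users <- c(
      if (n_bots > 0L) sprintf("ImportBot%d", seq_len(n_bots)),
      if (n_users - n_bots > 0L) runique(n_users - n_bots, rsurname)
    )
    is_bot_user <- c(rep(TRUE, n_bots), rep(FALSE, n_users - n_bots))

    titles <- paste0(runique(n_pages, rgenus), "_", runique(n_pages, repithet))
    art <- generate_article(seed = seed, n_treatments = 0)
    meta <- art$manifest$meta

    # One consecutive site-wide id sequence, interleaved across pages.
    base_id <- sample(100:999, 1)
    page_of <- c(seq_len(n_pages),
                 if (n_revisions > n_pages)
                   sample(n_pages, n_revisions - n_pages, replace = TRUE))
    if (n_pages > 1L && n_revisions > n_pages + 1L) {
      gaps <- vapply(seq_len(n_pages), function(p) {
        ids <- which(page_of == p)
        length(ids) > 1L && any(diff(ids) > 1L)
      }, logical(1))
      if (!any(gaps)) {  # force at least one non-consecutive run
        page_of[c(n_revisions - 1L, n_revisions)] <-
          page_of[c(n_revisions, n_revisions - 1L)]
      }
    }
    user_of <- integer(n_revisions)
    bot_idx <- which(is_bot_user)
    for (i in seq_len(n_revisions)) {
      user_of[i] <- if (i <= n_pages && length(bot_idx) > 0L) {
        bot_idx[1L]  # the import bot creates each page
      } else {
        sample.int(n_users, 1)
      }
    }
    t0 <- as.POSIXct("2011-04-14 10:00:00", tz = "UTC")
    timestamps <- t0 + cumsum(sample(60:7200, n_revisions, replace = TRUE))

    page_text <- character(n_pages)
    revisions <- vector("list", n_revisions)
    for (i in seq_len(n_revisions)) {
      p <- page_of[i]
      rid <- base_id + i - 1L
      if (!nzchar(page_text[p])) {
        cfg <- default_config()
        am <- article_meta(meta$authors, meta$year, meta$title, meta$journal,
                           meta$issue_no, meta$pages, meta$doi,
                           meta$publication_date)
        params <- citation_journal_params(am)
        params$date <- "{{REVISIONYEAR}}-{{REVISIONMONTH}}-{{REVISIONDAY2}}"
        params$revision <- "{{REVISIONID}}"
        params$contributors <- "{{CONTRIBUTORS}}"
        page_text[p] <- paste0(
          render_template_call(template_call(cfg$templates$citation, params)),
          sprintf("\n\nImported treatment text for %s.", titles[p]))
        comment <- "Automated import of the published treatment"
      } else {
        page_text[p] <- paste0(page_text[p], sprintf("\n\nEdit %d.", rid))
        comment <- sprintf("Synthetic edit %d", rid)
      }
      revisions[[i]] <- list(
        page = p, rev_id = rid, user = users[user_of[i]],
        is_bot = is_bot_user[user_of[i]],
        timestamp = format(timestamps[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        comment = comment, text = page_text[p]
      )
    }
    histories <- lapply(seq_len(n_pages), function(p) {
      revs <- Filter(function(r) r$page == p, revisions)
      list(title = gsub("_", " ", titles[p]),  # display form, as parsed back
           revisions = lapply(revs, function(r)
             r[c("rev_id", "user", "timestamp", "is_bot", "comment")]))
    })
    manifest <- list(seed = as.integer(seed), meta = meta,
                     users = stats::setNames(as.list(is_bot_user), users),
                     histories = histories)
    list(xml = build_dump_xml(titles, revisions, n_pages), manifest = manifest)
  })
}

build_dump_xml <- function(titles, revisions, n_pages) {
  doc <- xml2::xml_new_root(
    "mediawiki",
    xmlns = "http://www.mediawiki.org/xml/export-0.10/",
    version = "0.10", "xml:lang" = "en")
  for (p in seq_len(n_pages)) {
    pg <- xml2::xml_add_child(doc, "page")
    xml2::xml_add_child(pg, "title", gsub("_", " ", titles[p]))
    xml2::xml_add_child(pg, "ns", "0")
    xml2::xml_add_child(pg, "id", as.character(p))
    for (r in revisions) {
      if (r$page != p) next
      rv <- xml2::xml_add_child(pg, "revision")
      xml2::xml_add_child(rv, "id", as.character(r$rev_id))
      xml2::xml_add_child(rv, "timestamp", r$timestamp)
      ctr <- xml2::xml_add_child(rv, "contributor")
      xml2::xml_add_child(ctr, "username", r$user)
      xml2::xml_add_child(rv, "comment", r$comment)
      xml2::xml_add_child(rv, "text", r$text, "xml:space" = "preserve")
    }
  }
  as.character(doc)
}
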