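test_that("page_title joins name parts with underscores", {
  cases <- list(
    list(taxon_name("Sinocallipus", "catba"), "Sinocallipus_catba"),
    list(taxon_name("Neobidessodes", "darwiniensis"), "Neobidessodes_darwiniensis"),
    list(taxon_name("Anochetus", "boltoni"), "Anochetus_boltoni"),
    list(taxon_name("Abacus", "alba", "minor"), "Abacus_alba_minor"),
    list(taxon_name("Abacus"), "Abacus")
  )
  for (cs in cases) expect_identical(page_title(cs[[1]]), cs[[2]])
  expect_error(page_title("not a taxon"), class = "tp2w_validation_error")
})

test_that("external_links substitutes the encoded binomial in registry order", {
  reg <- registry_from_config(NULL)
  links <- external_links(taxon_name("Sinocallipus", "catba"), reg)
  expect_identical(nrow(links), length(reg$entries))
  expect_identical(nrow(links), 12L)  # default registry shipped in config
  expect_identical(links$resource[1], "GBIF")
  # space percent-encoded in every URL, per a reference encoding routine
  encoded <- utils::URLencode("Sinocallipus catba", reserved = TRUE)
  expect_true(all(grepl(encoded, links$url, fixed = TRUE)))
  expect_false(any(grepl(" ", links$url, fixed = TRUE)))
  # empty registry -> empty list; bad template rejected
  expect_identical(nrow(external_links(taxon_name("A", "b"),
                                       resource_registry(list()))), 0L)
  expect_error(resource_registry(list(list(name = "X", url = "http://x/"))),
               class = "tp2w_validation_error")
})

test_that("emit_key renders one table row per lead with linked outcomes", {
  key1 <- identification_key(list(list(number = 1L, leads = list(
    list(text = "Antenna long", taxon = "Genus alpha"),
    list(text = "Antenna short", taxon = "Genus beta")))))
  wt <- emit_key(key1)
  expect_identical(sum(gregexpr("|-", wt, fixed = TRUE)[[1]] > 0), 2L)
  expect_match(wt, "[[Genus_alpha]]", fixed = TRUE)
  expect_match(wt, "[[Genus_beta]]", fixed = TRUE)
  expect_true(isTRUE(wiki_check_markup(wt)))

  # dangling couplet reference is rejected, naming the couplet
  expect_error(
    identification_key(list(
      list(number = 1L, leads = list(
        list(text = "a", next_couplet = 2L),
        list(text = "b", taxon = "X y"))),
      list(number = 2L, leads = list(
        list(text = "c", next_couplet = 5L),
        list(text = "d", taxon = "Z w"))))),
    regexp = "couplet 2 refers to missing couplet 5",
    class = "tp2w_validation_error")

  # fixture key: row count equals total lead count in manifest
  fx <- generate_article(seed = 4, n_treatments = 3)
  art <- parse_article(fx$xml)
  mf <- fx$manifest$treatments[[3]]
  expect_false(is.null(mf$key_shape))
  wt3 <- emit_key(art$treatments[[3]]$keys[[1]])
  n_rows <- lengths(regmatches(wt3, gregexpr("\n|-", wt3, fixed = TRUE)))
  expect_identical(n_rows, mf$key_shape$n_leads)
})

test_that("emit_page lays out citation, classification, sections, links in order", {
  tr <- treatment(
    taxon = taxon_name("Sinocallipus", "catba", authorship = "Stoev & Enghoff, 2011"),
    sections = list(
      treatment_section("Description", list(list(type = "paragraph", text = "D"))),
      treatment_section("Distribution", list(list(type = "paragraph", text = "R")))),
    zoobank_lsid = "urn:lsid:zoobank.org:act:TEST")
  pg <- emit_page(tr, make_meta())
  expect_identical(pg$title, "Sinocallipus_catba")
  # citation template is the first non-whitespace construct
  expect_match(pg$markup, "^\\{\\{Cite treatment\n")
  pos <- function(pat) regexpr(pat, pg$markup, fixed = TRUE)
  expect_true(pos("{{Cite treatment") < pos("{{Taxon classification"))
  expect_true(pos("{{Taxon classification") < pos("== Description =="))
  expect_true(pos("== Description ==") < pos("== Distribution =="))
  expect_true(pos("== Distribution ==") < pos("{{External links"))
  expect_match(pg$markup, "zoobank.org/urn:lsid:zoobank.org:act:TEST", fixed = TRUE)
  expect_match(pg$markup, "doi = 10.9999/test.1.1", fixed = TRUE)
  expect_true(isTRUE(wiki_check_markup(pg$markup)))
})

test_that("zero-section treatment still carries the three structural templates", {
  tr <- treatment(taxon = taxon_name("Abacus", "alba"))
  pg <- emit_page(tr, make_meta())
  for (tpl in c("{{Cite treatment", "{{Taxon classification", "{{External links")) {
    expect_match(pg$markup, tpl, fixed = TRUE)
  }
  expect_true(isTRUE(wiki_check_markup(pg$markup)))
})

test_that("figures get page-derived wiki file names and appear in the images map", {
  fx <- generate_article(seed = 1, n_treatments = 3)
  art <- parse_article(fx$xml)
  idx <- which(vapply(fx$manifest$treatments, function(t) t$n_figures, integer(1)) == 2L)[1]
  expect_false(is.na(idx))
  pg <- emit_page(art$treatments[[idx]], art$meta)
  expect_identical(nrow(pg$images), 2L)
  expect_identical(pg$images$wiki_name,
                   sprintf("%s_fig%d.png", pg$title, 1:2))
  for (nm in pg$images$wiki_name) expect_match(pg$markup, nm, fixed = TRUE)
})

test_that("wiki-special characters in content are neutralised", {
  tr <- treatment(
    taxon = taxon_name("Abacus", "alba"),
    sections = list(treatment_section("Remarks", list(
      list(type = "paragraph", text = "Uses | and {{odd}} and [[link]] text")))))
  pg <- emit_page(tr, make_meta())
  expect_true(isTRUE(wiki_check_markup(pg$markup)))
  expect_match(pg$markup, "<nowiki>|</nowiki>", fixed = TRUE)
})

test_that("emitting an article yields one page per treatment; collisions are caught", {
  fx <- generate_article(seed = 6, n_treatments = 3)
  art <- parse_article(fx$xml)
  pages <- emit_article(art)
  expect_length(pages, 3L)
  for (pg in pages) expect_true(isTRUE(wiki_check_markup(pg$markup)))

  dup <- art
  dup$treatments <- art$treatments[c(1, 1)]
  expect_error(emit_article(dup), class = "tp2w_validation_error")
  pages2 <- emit_article(dup, config = list(title_collision = "suffix"))
  expect_length(unique(vapply(pages2, function(p) p$title, character(1))), 2L)
})

test_that("back-link property: citation carries the DOI and generic URL is base + /wiki/ + title", {
  fx <- generate_article(seed = 8, n_treatments = 2)
  art <- parse_article(fx$xml)
  for (i in seq_along(art$treatments)) {
    pg <- emit_page(art$treatments[[i]], art$meta)
    params <- parse_template_call(pg$markup, "Cite treatment")
    expect_identical(params$doi, art$meta$doi)
    expect_identical(generic_url(NULL, pg$title),
                     paste0("http://species-id.net/wiki/", pg$title))
  }
})

test_that("template calls reject duplicate keys and render deterministically", {
  expect_error(template_call("T", list(a = 1, a = 2)),
               class = "tp2w_validation_error")
  call <- template_call("T", list(a = "1", b = "x"))
  expect_identical(render_template_call(call), render_template_call(call))
  expect_identical(render_template_call(template_call("T")), "{{T}}")
})

test_that("wiki_check_markup flags unbalanced constructs", {
  expect_true(isTRUE(wiki_check_markup("{{a|b}} [[c]]")))
  bad <- wiki_check_markup("{{a|b} [[c]]")
  expect_false(isTRUE(bad))
  expect_match(attr(bad, "errors"), "unbalanced templates")
  expect_true(isTRUE(wiki_check_markup("<nowiki>{{</nowiki>")))
})
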