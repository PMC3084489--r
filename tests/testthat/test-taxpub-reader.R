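minimal_article_xml <- function(sections = '<treatment-sec sec-title="Description"><p>Text.</p></treatment-sec>') {
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<article dtd-version="tp-subset-1.0">
 <front>
  <journal-meta><journal-title>ZooKeys</journal-title></journal-meta>
  <article-meta>
   <title-group><article-title>T</article-title></title-group>
   <contrib-group><contrib><surname>Stoev</surname><given-names>P</given-names></contrib></contrib-group>
   <pub-date><day>14</day><month>04</month><year>2011</year></pub-date>
   <issue>90</issue><fpage>1</fpage><lpage>9</lpage>
   <article-id pub-id-type="doi">10.1/x</article-id>
  </article-meta>
 </front>
 <body>
  <taxon-treatment>
   <nomenclature>
    <taxon-name>
     <taxon-name-part part-type="genus">Sinocallipus</taxon-name-part>
     <taxon-name-part part-type="species">catba</taxon-name-part>
    </taxon-name>
    <taxon-authority>Stoev &amp; Enghoff, 2011</taxon-authority>
   </nomenclature>
   %s
  </taxon-treatment>
 </body>
</article>', sections)
}

test_that("minimal article parses into one treatment with one section", {
  art <- parse_article(minimal_article_xml())
  expect_s3_class(art, "taxpub_article")
  expect_length(art$treatments, 1L)
  expect_length(art$treatments[[1]]$sections, 1L)
  expect_identical(art$treatments[[1]]$sections[[1]]$label, "Description")
  expect_identical(art$meta$doi, "10.1/x")
  expect_identical(art$meta$pages, "1-9")
  expect_identical(art$meta$publication_date, as.Date("2011-04-14"))
})

test_that("treatment names come out in document order with parsed parts", {
  art <- parse_article(minimal_article_xml())
  names <- extract_treatment_names(art)
  expect_length(names, 1L)
  expect_identical(names[[1]]$genus, "Sinocallipus")
  expect_identical(names[[1]]$species_epithet, "catba")
  expect_identical(names[[1]]$rank, "species")
  expect_identical(names[[1]]$authorship, "Stoev & Enghoff, 2011")
  # zero-treatment article is valid and yields an empty list
  empty <- parse_article(generate_article(seed = 2, n_treatments = 0)$xml)
  expect_length(extract_treatment_names(empty), 0L)
})

test_that("section label order is preserved from the document", {
  labels <- c("Type locality", "Description", "Distribution", "Etymology")
  secs <- paste(sprintf(
    '<treatment-sec sec-title="%s"><p>x</p></treatment-sec>', labels),
    collapse = "\n")
  art <- parse_article(minimal_article_xml(secs))
  got <- vapply(art$treatments[[1]]$sections, function(s) s$label, character(1))
  expect_identical(got, labels)
})

test_that("parsed fixture matches the generator manifest", {
  fx <- generate_article(seed = 1, n_treatments = 3)
  art <- parse_article(fx$xml)
  expect_length(art$treatments, 3L)
  for (i in 1:3) {
    tr <- art$treatments[[i]]
    mf <- fx$manifest$treatments[[i]]
    expect_identical(tr$taxon$genus, mf$genus)
    expect_identical(tr$taxon$species_epithet, mf$species_epithet)
    expect_identical(vapply(tr$sections, function(s) s$label, character(1)),
                     mf$section_labels)
    expect_length(tr$figures, mf$n_figures)
    expect_length(tr$references, mf$n_references)
    expect_identical(tr$zoobank_lsid, mf$zoobank_lsid)
    if (is.null(mf$key_shape)) {
      expect_length(tr$keys, 0L)
    } else {
      expect_length(tr$keys[[1]]$couplets, mf$key_shape$n_couplets)
    }
  }
})

test_that("malformed XML and missing mandatory fields raise typed errors", {
  expect_error(parse_article("<article><front>"), class = "tp2w_parse_error")
  no_authors <- sub("<contrib>.*</contrib>", "", minimal_article_xml())
  no_authors <- sub("<journal-title>ZooKeys</journal-title>",
                    "<journal-title></journal-title>", no_authors)
  err <- tryCatch(parse_article(no_authors), condition = function(c) c)
  expect_s3_class(err, "tp2w_validation_error")
  expect_setequal(err$fields, c("authors", "journal"))
})

test_that("unknown elements are flattened to text with a warning, never dropped", {
  xml <- minimal_article_xml(
    '<treatment-sec sec-title="Description"><p>Known.</p><weird-tag>Lost words</weird-tag></treatment-sec>')
  expect_warning(art <- parse_article(xml), class = "tp2w_unknown_element")
  blocks <- art$treatments[[1]]$sections[[1]]$blocks
  expect_length(blocks, 2L)
  expect_identical(blocks[[2]]$type, "paragraph")
  expect_identical(blocks[[2]]$text, "Lost words")
})

test_that("parsing is deterministic and conserves treatment count", {
  fx <- generate_article(seed = 5, n_treatments = 4)
  expect_identical(parse_article(fx$xml), parse_article(fx$xml))
  expect_length(parse_article(fx$xml)$treatments,
                length(fx$manifest$treatments))
})

test_that("shipped example documents validate and parse", {
  examples <- list.files(system.file("extdata", package = "taxpub2wiki"),
                         pattern = "^example-.*\\.xml$", full.names = TRUE)
  expect_gte(length(examples), 3L)
  for (path in examples) {
    expect_true(validate_taxpub(path))
    art <- parse_article(path)
    expect_s3_class(art, "taxpub_article")
  }
  hand <- parse_article(system.file(
    "extdata", "example-sinocallipus-synthetic.xml", package = "taxpub2wiki"))
  expect_identical(format(hand$treatments[[1]]$taxon), "Sinocallipus catba")
})

test_that("taxon_name normalises case and derives rank", {
  tn <- taxon_name("sinocallipus", "CATBA")
  expect_identical(tn$genus, "Sinocallipus")
  expect_identical(tn$species_epithet, "catba")
  expect_identical(taxon_name("Abc")$rank, "genus")
  expect_identical(taxon_name("Abc", "d", "e")$rank, "subspecies")
  expect_error(taxon_name("Abc", infraspecific_epithet = "x"),
               class = "tp2w_validation_error")
  expect_error(taxon_name(""), class = "tp2w_validation_error")
})
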