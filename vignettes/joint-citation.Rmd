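---
title: "Joint journal + wiki citation of taxon treatments: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint journal + wiki citation of taxon treatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxpub2wiki)
```

## The model

A taxon treatment lives twice: as part of a static journal article and
as a dynamic wiki page derived from it. `taxpub2wiki` treats the bridge
between them as three formal objects.

**The article** is an ordered container: bibliographic metadata (authors,
year, title, journal, issue, pages, DOI, publication date) plus a list
of treatments, each carrying a scientific name with authorship, an
optional nomenclatural-act LSID, labelled sections in document order,
references, figures and dichotomous keys. The parser consumes a pinned,
namespace-free TaxPub/NLM-style element subset (XSD shipped in
`inst/extdata/`): the family of DTDs this emulates is large and
evolving, and pinning a minimal vocabulary keeps the parser, the schema
and the fixture generator in lockstep. Everything inside that subset is
parsed structurally; unknown elements inside a section are flattened to
paragraph text with a warning — legacy markup varies, and
lossy-but-logged beats brittle.

**The page history** is a page title plus revisions ordered by a
site-wide revision id: on one MediaWiki installation, revision numbers
form a single consecutive sequence over *all* pages, so a page's own ids
are increasing but gappy. This site-wide id is exactly what the `oldid=`
query parameter of a permanent link takes, which is why it, and not a
per-page counter, appears in citations.

**The joint citation** combines both: the journal half verbatim from the
article metadata, and a wiki half consisting of the UTC date of the
cited revision, its revision number, the permanent URL, and the
contributor list. Attribution is by revision participation: the
contributors to revision `r` are the deduplicated users of all revisions
with id ≤ `r`. The phrase "contributed to the currently displayed
version as well as to all earlier versions" admits, in principle, an
intersection reading (users present in every version); we reject it as
nonsensical — the first author of a page would be disqualified by any
later edit — and implement the prefix-union reading, which also gives
the useful monotonicity property that the contributor set can only grow
with the revision number.

## Parameters that matter

* `site$base_url` (default `http://species-id.net`) and
  `site$script_path` (default `/w`) define the two URL forms: generic
  `base/wiki/<Title>` and permanent
  `base<script>/index.php?title=<Title>&oldid=<rev>`. The script path is
  configuration because real MediaWiki installations differ (`/w` vs
  `/wiki` vs empty), and published examples themselves vary between the
  two spellings.
* `exclude_bots` (default `TRUE` in citations). Dumps carry no bot
  flag, so accounts are classified by the configurable `bot_pattern`
  (default `[Bb]ot[0-9]*$`). The default excludes bots because the page
  is created by an import bot whose content is already credited to the
  journal authors in the other half of the same reference; crediting
  "ImportBot1" alongside them would double-count machinery. Anonymous
  editors are credited verbatim as their IP string (MediaWiki
  convention).
* Contributor ordering: alphabetical, case-insensitive with a
  case-sensitive tiebreak, computed with radix sort in the C locale —
  reproducible across systems, which a locale-dependent collation is
  not.
* `empty_contributors_token` (default `"none"`): a page no human has
  touched still needs a syntactically complete citation.
* `title_collision` (default `"error"`): two treatments of the same
  binomial in one article indicate either an input error or a genuine
  redescription; refusing with a disambiguation error is the safe
  default, and the `"suffix"` policy (`Title_(Authorship)`, then a
  numeric suffix) is available for the redescription case.
* The external-resource registry ships 12 default entries (GBIF, EOL,
  NCBI, PubMed, BHL, ZooBank, IPNI, Index Fungorum, Tropicos, PLANTS,
  Wikispecies, Wikipedia), each a URL template with exactly one `{name}`
  placeholder substituted with the percent-encoded taxon name. Links
  are generated, never resolved: no network is touched anywhere.

## Rendering choices

The emitted page puts the citation template first — the recommended
citation must be the first thing a reader (or a re-importer) encounters —
followed by the classification template, the sections as level-2
headings (the page title is the level-1 heading in MediaWiki), keys,
figures, references and the external-links template. The wiki-side
template parameters are emitted as MediaWiki magic words
(`{{REVISIONID}}`, `{{REVISIONYEAR}}-…`, `{{CONTRIBUTORS}}`), so the
live template always displays the version the reader is looking at;
`citation_template_call()` can instead pin concrete values for a cited
revision. Free text is escaped with `<nowiki>` spans wherever it could
break template or table syntax, and every emitted page is checked for
balanced `{{ }}`/`[[ ]]` pairs. Author names render as
"Surname Initials" joined by commas, the reference style of the
taxonomic journals this targets; BibTeX gets "Surname, I." joined by
`and`, with the entire wiki half carried in the `note` field so that any
BibTeX consumer preserves it; RIS uses `N1` the same way. Reference
lists render as plain formatted lines under a "References" heading —
the smallest faithful rendering; per-entry citation templates would
impose a bibliography model the source markup does not contain. Figure
files are renamed `<PageTitle>_fig<N>.<ext>`, a deterministic rule the
source naming cannot collide with.

## What the synthetic generators emulate — and what they do not

`generate_article()` emulates an XML-first taxonomic journal article:
2–4 authors, a publication year in 2009–2011 (the era of the workflow
this models), treatments with pronounceable pseudo-Latin binomials
unique within the article, 3–4 sections drawn in canonical order from a
fixed label pool ({Type locality, Description, Distribution, Etymology,
Diagnosis, Ecology, Materials examined, Remarks} — the label set is
open in real documents and treated as such by the parser), 0–2 figure
stubs, 1–3 references, and a 3-couplet dichotomous key on every third
treatment. `generate_history()` emulates a wiki hosting imported
treatments: one consecutive site-wide id sequence interleaved over the
pages, strictly increasing timestamps starting at the (synthetic)
publication day, a user pool with a configurable bot fraction (default
0.2 — one bot in a pool of five, matching an import-bot-plus-editors
community), the first revision of each page performed by the import bot
and embedding the citation template, so a joint citation is derivable
from the dump alone. Each generator draws from its own seeded RNG
stream and restores the session RNG, so fixtures are byte-reproducible
and mutually independent.

They do **not** emulate: real biological prose, image binaries (figures
are metadata stubs), deleted or oversighted revisions, page moves and
redirects, or edit conflicts. A green test therefore establishes the
structural and arithmetic correctness of parsing, conversion,
attribution and rendering — not robustness to the full wildness of a
production wiki database.

## Numerical and degenerate-input choices

Dates are handled in UTC throughout; the citation date is the UTC date
of the cited revision's timestamp, not the access date. Revisions that
appear out of order in a dump are reordered by id with a warning; a page
with no revisions is an error. An article with zero treatments is valid
and converts to zero pages (with a logged warning). A rev id absent from
a page's history is a lookup error, not an empty result. Duplicate
revision ids across a dump are rejected — they would violate the
site-wide numbering that permanent links rely on.

## Known limitations

* The TaxPub subset is deliberately minimal; full NLM/JATS or taxonX
  documents must be down-converted before use.
* Attribution is by revision participation, not by surviving text:
  a contributor whose edit was later reverted is still credited.
* BibTeX output targets the common "article + note" pattern; strict
  BibTeX escaping covers braces only, which suffices for the fixture
  vocabulary but not for arbitrary LaTeX-hostile titles.
* Metadata recovery from a dump (`cmd_cite` without `--article`)
  assumes the citation template layout this package emits and
  single-token surnames in the `authors` parameter.
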