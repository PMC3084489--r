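# taxpub2wiki

A journal-to-wiki publishing bridge for taxonomic treatments.

## The problem

Taxonomic knowledge is published twice over: once as a static,
time-stamped journal article (required for nomenclatural validity and a
permanent record), and increasingly again as a living wiki page that the
community keeps correcting and extending. The two worlds cite badly
across the gap. A wiki page is usually cited as a bare URL with a "date
of accession", which ignores that every MediaWiki edit is versioned,
numbered site-wide and publicly attributed — and it credits neither the
authors of the original description nor the wiki editors who improved it.

`taxpub2wiki` implements the full bridge for users running a
treatment-wiki workflow (publishers, wiki operators, biodiversity
informaticians):

1. **Converter** — fragments an XML-first taxonomic article (a pinned
   TaxPub/NLM-style element subset; schema in
   `inst/extdata/taxpub-subset.xsd`) into one MediaWiki page per taxon
   treatment: citation and classification templates at the top, one
   level-2 heading per treatment section in source order, dichotomous
   keys as wiki tables, figures, reference lists, and a hub of links to
   external biodiversity resources (GBIF, EOL, NCBI, ZooBank, ...).
   Output is inert: wikitext files plus a JSON upload plan a bot could
   later execute.
2. **Versioned-citation engine** — parses standard MediaWiki XML export
   dumps and, for any revision `r` of a page, computes the attribution
   set (all users of revisions with id ≤ `r`, bots excluded by default,
   alphabetically sorted) and builds the **joint citation**, a single
   reference crediting both halves:

   ```
   <Authors> (<year>) <Title>. <Journal> <Issue>: <pages>. doi:<DOI>.
   Versioned wiki page: <YYYY-MM-DD>, version <rev>,
   <base><script>/index.php?title=<Genus_species>&oldid=<rev>,
   contributors (alphabetical order): <C1, C2, ...>.
   ```

   Renderers exist for plain text, BibTeX, RIS and a wikitext
   cite-template call.
3. **Synthetic fixtures** — deterministic generators for both input
   formats with ground-truth manifests, so the whole pipeline is
   testable offline.

Two URL forms matter throughout: the **generic link**
`base/wiki/<Title>` always resolves to the newest page version, while
the **permanent link** `base<script>/index.php?title=<Title>&oldid=<rev>`
pins one site-wide-numbered revision.

## Worked example

```r
library(taxpub2wiki)

# 1. Convert an article: one wiki page per treatment
art <- parse_article(system.file("extdata",
        "example-sinocallipus-synthetic.xml", package = "taxpub2wiki"))
pg <- emit_page(art$treatments[[1]], art$meta)
pg$title
#> [1] "Sinocallipus_catba"
generic_url(NULL, pg$title)
#> [1] "http://species-id.net/wiki/Sinocallipus_catba"

# 2. Attribute contributors from a (synthetic) export dump
hx <- generate_history(seed = 7, n_pages = 2, n_revisions = 10)
h <- parse_export(hx$xml)[[1]]
h$revisions[, c("rev_id", "user", "is_bot")]
#>   rev_id       user is_bot
#> 1    231 ImportBot1   TRUE
#> 2    234       Veli  FALSE
#> 3    237       Veli  FALSE

# 3. The joint citation for the latest revision
cit <- build_joint_citation(art$meta, h, "latest")
cat(render_citation(cit, "text"))
#> Stoev P, Enghoff H (2011) A review of the millipede genus Sinocallipus,
#> with notes on cave-dwelling species. ZooKeys 90: 13-34.
#> doi:10.9999/synthetic.90.0001. Versioned wiki page: 2011-04-14,
#> version 237, http://species-id.net/w/index.php?title=Themaops_siplianiella&oldid=237,
#> contributors (alphabetical order): Veli.
```

Note how the revision number after `version` and inside `oldid=` agree,
the date is the UTC date of that revision, and the import bot
(`ImportBot1`) is not credited — the journal authors already are.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli","taxpub2wiki.R",package="taxpub2wiki"))')
Rscript $CLI convert  article.xml -o outdir [--config cfg.yaml]
Rscript $CLI backlink article.xml          # "taxon<TAB>generic URL" per treatment
Rscript $CLI cite     dump.xml --page Genus_species [--rev N|latest] \
                      [--format text|bibtex|ris|wikitext]
Rscript $CLI fixtures article|history [--seed N] [--n N] [--out path]
```

Exit codes: 0 success, 1 parse/validation failure, 2 usage error. Logs
go to stderr, data to stdout.

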