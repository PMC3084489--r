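# Default configuration for the journal-to-wiki converter.
site:
  base_url: "http://species-id.net"
  # MediaWiki script path used in permanent (oldid) links; the generic
  # pretty-URL path is always /wiki/.
  script_path: "/w"
templates:
  citation: "Cite treatment"
  classification: "Taxon classification"
  external_links: "External links"
  wikitext_cite: "cite journal"
# What to do when two treatments map onto the same page title:
# "error" refuses the conversion, "suffix" appends _(Authorship).
title_collision: "error"
# Usernames matching this regular expression are treated as bot accounts
# when attributing contributors (MediaWiki dumps carry no bot flag).
bot_pattern: "[Bb]ot[0-9]*$"
# Empty contributor lists render as this token in citations.
empty_contributors_token: "none"
# External biodiversity resources linked from every taxon page; {name}
# is replaced by the URL-encoded taxon name.
resources:
  - name: "GBIF"
    url: "http://www.gbif.org/species/search?q={name}"
  - name: "EOL"
    url: "http://eol.org/search?q={name}"
  - name: "NCBI"
    url: "http://www.ncbi.nlm.nih.gov/taxonomy/?term={name}"
  - name: "PubMed"
    url: "http://www.ncbi.nlm.nih.gov/pubmed/?term={name}"
  - name: "BHL"
    url: "http://www.biodiversitylibrary.org/name/{name}"
  - name: "ZooBank"
    url: "http://zoobank.org/Search?search_term={name}"
  - name: "IPNI"
    url: "http://www.ipni.org/search?q={name}"
  - name: "Index Fungorum"
    url: "http://www.indexfungorum.org/names/Names.asp?SearchTerm={name}"
  - name: "Tropicos"
    url: "http://www.tropicos.org/NameSearch.aspx?name={name}"
  - name: "PLANTS"
    url: "http://plants.usda.gov/home/nameSearch?keywordsearch={name}"
  - name: "Wikispecies"
    url: "http://species.wikimedia.org/wiki/{name}"
  - name: "Wikipedia"
    url: "http://en.wikipedia.org/wiki/{name}"
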