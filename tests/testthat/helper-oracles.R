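# Independent oracles and small builders shared across the suite.
# Nothing here calls the code path it is used to check.

# Single-reference grammar transcribed once from the joint-citation
# scheme: journal half, then the literal "Versioned wiki page:" marker,
# date, version number, permanent oldid URL, and the alphabetical
# contributor list.
SCHEME_REGEX <- paste0(
  "^.+ \\(\\d{4}\\) .+\\. ",
  "Versioned wiki page: \\d{4}-\\d{2}-\\d{2}, ",
  "version \\d+, ",
  "http://\\S+\\?title=\\S+&oldid=\\d+, ",
  "contributors \\(alphabetical order\\): .+\\.$"
)

# Brute-force prefix-union oracle for contributor attribution: walk the
# revisions one by one, accumulate users, then selection-sort with an
# explicit comparator (case-insensitive, case-sensitive tiebreak).
contributors_oracle <- function(revisions, rev_id, exclude_bots = TRUE) {
  acc <- character()
  for (i in seq_len(nrow(revisions))) {
    r <- revisions[i, ]
    if (r$rev_id > rev_id) next
    if (exclude_bots && r$is_bot) next
    if (!r$user %in% acc) acc <- c(acc, r$user)
  }
  lt <- function(a, b) {
    la <- tolower(a); lb <- tolower(b)
    if (la != lb) return(la < lb)
    a < b
  }
  out <- character()
  while (length(acc) > 0) {
    m <- 1L
    for (j in seq_along(acc)) if (lt(acc[j], acc[m])) m <- j
    out <- c(out, acc[m])
    acc <- acc[-m]
  }
  out
}

# Minimal independent BibTeX entry parser: entry type, key, and
# `name = {value}` fields (values free of unescaped braces).
parse_bibtex_min <- function(text) {
  head_match <- regmatches(text, regexec("@([A-Za-z]+)\\{([^,]+),", text))[[1]]
  stopifnot(length(head_match) == 3L)
  fields <- list()
  for (line in strsplit(text, "\n")[[1]]) {
    mm <- regmatches(line, regexec("^ *([A-Za-z]+) *= *\\{(.*)\\},? *$", line))[[1]]
    if (length(mm) == 3L) fields[[mm[2]]] <- gsub("\\\\([{}])", "\\1", mm[3])
  }
  list(type = head_match[2], key = head_match[3], fields = fields)
}

# Minimal independent RIS parser: list of (tag, value) in file order.
parse_ris_min <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  tags <- character(); values <- character()
  for (line in lines) {
    mm <- regmatches(line, regexec("^([A-Z][A-Z0-9])  - (.*)$", line))[[1]]
    if (length(mm) == 3L) {
      tags <- c(tags, mm[2]); values <- c(values, mm[3])
    }
  }
  data.frame(tag = tags, value = values, stringsAsFactors = FALSE)
}

make_meta <- function(doi = "10.9999/test.1.1") {
  article_meta(
    authors = data.frame(surname = c("Stoev", "Enghoff"),
                         given = c("P", "H"), stringsAsFactors = FALSE),
    year = 2011, title = "A cave-dwelling millipede", journal = "ZooKeys",
    issue_no = "90", pages = "13-34", doi = doi,
    publication_date = as.Date("2011-04-14")
  )
}

make_history <- function(revs) {
  # revs: list of c(rev_id, user) or list(rev_id=, user=, is_bot=)
  df <- do.call(rbind, lapply(seq_along(revs), function(i) {
    r <- revs[[i]]
    data.frame(rev_id = as.integer(r$rev_id), user = r$user,
               is_bot = isTRUE(r$is_bot),
               timestamp = as.POSIXct("2011-04-14 10:00:00", tz = "UTC") +
                 3600 * i,
               comment = "", text = "", stringsAsFactors = FALSE)
  }))
  page_history("Test page", df)
}

write_fixture <- function(xml, dir = withr::local_tempdir(.local_envir = parent.frame()),
                          name = "fixture.xml") {
  path <- file.path(dir, name)
  writeLines(xml, path, sep = "", useBytes = TRUE)
  path
}
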