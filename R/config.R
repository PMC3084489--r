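#' Site and conversion configuration
#'
#' One YAML file drives the whole pipeline: the wiki site layout (base URL
#' and MediaWiki script path), the names of the wiki templates the emitter
#' calls, the title-collision policy, the bot-account recognition pattern
#' and the registry of external biodiversity resources linked from every
#' taxon page. [default_config()] returns the configuration shipped with
#' the package; [load_config()] reads a user file and fills any gaps with
#' the defaults.
#'
#' @param path path to a YAML configuration file.
#' @return A nested list of class `site_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort_usage(sprintf("config file not found: %s", path))
  }
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' @rdname load_config
#' @export
default_config <- function() {
  path <- system.file("extdata", "default-config.yaml", package = "taxpub2wiki")
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "site_config"
  cfg
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) && nm != "resources") {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  class(base) <- "site_config"
  base
}

as_config <- function(config) {
  if (is.null(config)) return(default_config())
  if (inherits(config, "site_config")) return(config)
  if (is.character(config) && length(config) == 1L) return(load_config(config))
  if (is.list(config)) return(merge_config(default_config(), config))
  abort_usage("config must be NULL, a site_config, a list, or a YAML path")
}

#' External-resource link registry
#'
#' Ordered set of biodiversity resources (GBIF, EOL, NCBI, PubMed, BHL,
#' ZooBank, IPNI, Index Fungorum, Tropicos, PLANTS, Wikispecies,
#' Wikipedia, ...) each with a URL template containing exactly one
#' `{name}` placeholder for the taxon name.
#'
#' @param entries list of lists with fields `name` and `url`.
#' @return An object of class `resource_registry`.
#' @export
resource_registry <- function(entries) {
  for (e in entries) {
    n_ph <- lengths(regmatches(e$url, gregexpr("\\{name\\}", e$url, fixed = FALSE)))
    if (n_ph != 1L) {
      abort_validation(sprintf(
        "registry entry '%s' must contain exactly one {name} placeholder", e$name))
    }
  }
  structure(list(entries = entries), class = "resource_registry")
}

#' @rdname resource_registry
#' @param config a configuration object (see [load_config()]).
#' @export
registry_from_config <- function(config = NULL) {
  cfg <- as_config(config)
  resource_registry(cfg$resources)
}
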