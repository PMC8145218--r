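# Internal helpers shared across modules.

split_geo_path <- function(path) strsplit(path, ">", fixed = TRUE)

geo_path_depth <- function(path) lengths(split_geo_path(path))

# TRUE when `prefix` names the same unit as `path` or one of its ancestors.
# Paths are ">"-joined place names rooted at the country.
is_path_prefix <- function(prefix, path, strict = FALSE) {
  a <- split_geo_path(prefix)[[1L]]
  b <- split_geo_path(path)[[1L]]
  if (length(a) > length(b)) return(FALSE)
  if (strict && length(a) == length(b)) return(FALSE)
  all(a == b[seq_along(a)])
}

# Render a decimal year back to the text form parse_year() accepts:
# whole years as "2016", mid-coded years as "2013.5".
format_year <- function(year) {
  ifelse(year %% 1 == 0, sprintf("%d", as.integer(year)), sprintf("%.1f", year))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
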