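# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators (fixtures)
#' never perturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else if
      (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Read a text table file: drops '#' comment lines and blank lines, keeps the
# original line numbers for error messages. Returns list(lines, lineno).
read_body_lines <- function(path) {
  if (!file.exists(path)) stop2("file not found: '%s'", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  list(lines = raw[keep], lineno = which(keep))
}

# Split kept lines on tabs; returns list of character vectors. A sentinel
# is appended before splitting so trailing blank cells survive (strsplit
# drops trailing empty strings).
split_tsv <- function(lines) {
  if (!length(lines)) return(list())
  parts <- strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE)
  lapply(parts, function(r) r[-length(r)])
}

# Deterministic, locale-independent number formatting for SVG attributes.
fmt_num <- function(x) {
  out <- formatC(x, format = "f", digits = 2, decimal.mark = ".")
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

# Compact significant-digit formatting for values shown in legends/titles.
fmt_val <- function(x) formatC(x, format = "g", digits = 6)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Write lines as UTF-8 with '\n' separators (byte-stable across platforms).
write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
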