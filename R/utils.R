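# Internal helpers shared across modules.

stop_varkin <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "varkin_error"), ...)
}

# enum check with a helpful message; `facet` names the vocabulary in errors
check_tokens <- function(x, allowed, facet) {
  bad <- setdiff(x, allowed)
  if (length(bad) > 0) {
    stop_varkin(
      sprintf(
        "unknown %s token(s): %s (allowed: %s)",
        facet, paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
      ),
      class = "varkin_validation_error"
    )
  }
  invisible(x)
}

# write a text file atomically: temp file in the same directory, then rename
atomic_write <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop_varkin(sprintf("output directory does not exist: %s", dir),
                class = "varkin_io_error")
  }
  tmp <- tempfile(pattern = ".varkin-", tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wb")
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  close(con)
  if (!file.rename(tmp, path)) {
    stop_varkin(sprintf("cannot write output file: %s", path),
                class = "varkin_io_error")
  }
  invisible(path)
}

# deterministic number formatting for SVG output
fmt_num <- function(x) sprintf("%.6f", x)

# xml-escape the five predefined entities
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a plain tibble: strips any extra classes and attributes that subsetting
# or joins may have carried over from a source object
bare_tibble <- function(df) {
  out <- as_tibble(df)
  keep <- c("names", "row.names", "class")
  for (nm in setdiff(names(attributes(out)), keep)) {
    attr(out, nm) <- NULL
  }
  class(out) <- class(tibble())
  out
}
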